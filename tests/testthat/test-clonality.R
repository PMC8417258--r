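# shared simulated sample for the clonality stage (two clones, distinct Vs)
local({
  db <- test_db()
  sp1 <- productive_spec(db, v_idx = 1, abundance = 0.65)
  sp2 <- productive_spec(db, v_idx = 5, abundance = 0.35, d_idx = 2)
  .fixture_cache$clon_sam <- simulate_sample(db, list(sp1, sp2), 600,
                                             error_model(), rng_seed = 21)
  .fixture_cache$clon_aln <- align_reads(.fixture_cache$clon_sam$reads, db)
})

test_that("depth is mean per-base coverage over the gene interval", {
  db <- test_db()
  vg <- db_genes(db, "V")

  # no alignments -> all zero, every V gene present
  d0 <- compute_depth(.fixture_cache$clon_aln[0, ], db)
  expect_equal(d0$gene, vg$name)
  expect_true(all(d0$depth == 0))

  # constructed alignments exactly covering one gene
  aln <- data.frame(read_id = sprintf("r%d", 1:100), gene = vg$name[2],
                    contig = db$contig_id, r_start = vg$start[2],
                    r_end = vg$end[2], strand = "+",
                    stringsAsFactors = FALSE)
  d <- compute_depth(aln, db)
  expect_equal(d$depth[d$gene == vg$name[2]], 100)
  expect_equal(d$n_reads[d$gene == vg$name[2]], 100)
  expect_true(all(d$depth[d$gene != vg$name[2]] == 0))

  # conservation: sum of depth x length never exceeds total aligned bases
  aln2 <- .fixture_cache$clon_aln
  dd <- compute_depth(aln2, db)
  glen <- vg$end - vg$start
  expect_lte(sum(dd$depth * glen), sum(aln2$r_end - aln2$r_start))
})

test_that("clonal calling applies the coverage threshold inclusively", {
  d <- data.frame(gene = c("IGHV3-23", "IGHV1-69"), depth = c(501, 499),
                  n_reads = c(501L, 499L), stringsAsFactors = FALSE)
  calls <- call_clonal_genes(d, threshold = 500)
  expect_equal(calls$gene[calls$passed], "IGHV3-23")

  d$depth <- c(500, 499)
  expect_true(call_clonal_genes(d, 500)$passed[1])  # boundary is inclusive

  d$depth <- c(0, 0)
  expect_false(any(call_clonal_genes(d, 500)$passed))

  expect_error(call_clonal_genes(d, 0), "threshold")

  # monotonicity: raising the threshold never adds a call
  dd <- compute_depth(.fixture_cache$clon_aln, test_db())
  prev <- Inf
  for (thr in c(50, 150, 300, 450, 600)) {
    n <- sum(call_clonal_genes(dd, thr)$passed)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("simulated clones put the coverage peak on the true V genes", {
  sam <- .fixture_cache$clon_sam
  dd <- compute_depth(.fixture_cache$clon_aln, test_db())
  top2 <- dd$gene[order(-dd$depth)][1:2]
  expect_setequal(top2, sam$clones$v_name)
  # dominant clone ranks first
  expect_equal(dd$gene[which.max(dd$depth)], sam$clones$v_name[1])
})

test_that("read selection follows the 50%-overlap rule and orients reads", {
  db <- test_db()
  vg <- db_genes(db, "V")
  g <- vg[2, ]
  aln <- data.frame(
    read_id = c("full", "tiny"), gene = g$name, contig = db$contig_id,
    r_start = c(g$start, g$start),
    r_end = c(g$end, g$start + round(0.1 * (g$end - g$start))),
    strand = c("-", "+"), stringsAsFactors = FALSE)
  reads <- data.frame(read_id = c("full", "tiny"),
                      seq = c(revcomp(g$sequence), substr(g$sequence, 1, 30)),
                      stringsAsFactors = FALSE)
  cl <- select_reads(aln, g$name, db, reads)
  expect_equal(cl$read_id, "full")          # 10% overlap excluded
  expect_equal(cl$seq, g$sequence)          # minus strand re-oriented

  aln0 <- aln[aln$read_id == "tiny", ]
  expect_error(select_reads(aln0, g$name, db, reads), "consistency")
})

test_that("per-gene clusters agree with the simulator's read-clone map", {
  db <- test_db()
  sam <- .fixture_cache$clon_sam
  aln <- .fixture_cache$clon_aln
  for (ci in 1:2) {
    gene <- sam$clones$v_name[ci]
    cid <- sam$clones$clone_id[ci]
    cl <- select_reads(aln, gene, db, sam$reads)
    truth_ids <- sam$read_map$read_id[sam$read_map$clone_id == cid]
    agreement <- mean(cl$read_id %in% truth_ids)
    expect_gte(agreement, 0.95)
    # and the cluster recovers most of the clone
    expect_gte(length(intersect(cl$read_id, truth_ids)) / length(truth_ids),
               0.9)
  }
})

test_that("a 90%-identical same-family pair still peaks on the true gene", {
  db <- test_db()
  vg <- db_genes(db, "V")
  fam <- vg[vg$family == vg$family[1], ]
  expect_equal(nrow(fam), 2)
  id <- 100 * sw_align(fam$sequence[1], fam$sequence[2])$identity
  expect_gt(id, 85)  # the confusable regime
  for (v_idx in which(vg$name %in% fam$name)) {
    sp <- productive_spec(db, v_idx = v_idx)
    sam <- simulate_sample(db, list(sp), 300, error_model(), rng_seed = 31)
    dd <- compute_depth(align_reads(sam$reads, db), db)
    expect_equal(dd$gene[which.max(dd$depth)], vg$name[v_idx])
  }
})
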