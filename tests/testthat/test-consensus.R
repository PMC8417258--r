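test_that("tolerance schedules are validated", {
  expect_silent(tolerance_schedule(c(0.05, 0.1)))
  expect_error(tolerance_schedule(numeric(0)), "non-empty")
  expect_error(tolerance_schedule(c(0.1, 0.1)), "increasing")
  expect_error(tolerance_schedule(c(0.1, 0.6)), "in \\(0, 0.5\\)")
})

test_that("greedy subclustering separates divergent templates", {
  # identical reads: one partition
  cl <- make_cluster(rep(random_seq(200), 10))
  sc <- subcluster(cl, 0.05)
  expect_length(sc$partitions, 1)
  expect_length(sc$partitions[[1]], 10)

  # two templates at ~30% divergence, error-free reads: perfect split
  withr::with_seed(5, {
    t1 <- random_seq(300)
    ch <- strsplit(t1, "")[[1]]
    flip <- sample(300, 90)
    ch[flip] <- vapply(ch[flip], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
    t2 <- paste(ch, collapse = "")
  })
  cl2 <- make_cluster(c(rep(t1, 6), rep(t2, 6)))
  sc2 <- subcluster(cl2, 0.05)
  expect_length(sc2$partitions, 2)
  expect_setequal(lengths(sc2$partitions), c(6, 6))
  sets <- lapply(sc2$partitions, function(i) sort(unique(cl2$seq[i])))
  expect_setequal(unlist(lapply(sets, length)), c(1, 1))

  # deterministic
  expect_identical(sc2, subcluster(cl2, 0.05))
})

test_that("escalation stops at the earliest succeeding tolerance", {
  # solvable at schedule[1]: error-free identical reads
  cl <- make_cluster(rep(random_seq(250), 30))
  recs <- build_consensus(cl, schedule = c(0.05, 0.10), min_support = 3)
  expect_equal(recs$status, "ok")
  expect_equal(recs$tolerance, 0.05)
  expect_equal(recs$sequence, cl$seq[1])
  expect_equal(recs$support, 30)

  # 10%-error reads are too spread for 0.05 but assemble at 0.10
  tpl <- withr::with_seed(8, random_seq(363))
  rr <- simulate_reads(tpl, 120, error_model(), rng_seed = 8)
  cl2 <- make_cluster(oriented_reads(rr))
  recs2 <- build_consensus(cl2, min_support = 20)
  expect_equal(unique(recs2$status), "ok")
  expect_equal(unique(recs2$tolerance), 0.10)
})

test_that("support filtering yields auditable failures, never silent drops", {
  cl <- make_cluster(rep(random_seq(100), 2))
  recs <- build_consensus(cl, min_support = 3)
  expect_equal(recs$status, "filtered_low_support")
  expect_equal(recs$reason, "cluster_below_min_support")
  expect_equal(recs$sequence, "")

  # enough reads but no partition can gather min_support
  withr::with_seed(3, seqs <- vapply(1:30, function(i) random_seq(150), ""))
  cl2 <- make_cluster(seqs)  # 30 mutually unrelated reads
  recs2 <- build_consensus(cl2, min_support = 20)
  expect_equal(recs2$status, "failed")
  expect_equal(recs2$reason, "no_partition_reached_min_support")
})

test_that("raising min_support never increases the number of ok records", {
  tpl <- withr::with_seed(13, random_seq(350))
  rr <- simulate_reads(tpl, 60, error_model(), rng_seed = 13)
  cl <- make_cluster(oriented_reads(rr))
  prev <- Inf
  for (ms in c(5, 20, 40, 70)) {
    recs <- build_consensus(cl, min_support = ms)
    n_ok <- sum(recs$status == "ok")
    expect_lte(n_ok, prev)
    prev <- n_ok
  }
})

test_that("draft consensus from noisy reads is near-exact before polishing", {
  tpl <- withr::with_seed(29, random_seq(363))
  rr <- simulate_reads(tpl, 200, error_model(), rng_seed = 29)
  recs <- build_consensus(make_cluster(oriented_reads(rr)), min_support = 20)
  expect_equal(recs$status[1], "ok")
  expect_lte(as.integer(adist(recs$sequence[1], tpl)), 2)
  # length within +-3 nt of the template at this depth
  expect_lte(abs(nchar(recs$sequence[1]) - nchar(tpl)), 3)
})

test_that("polishing is a fixed point on clean data and corrects drafts", {
  tpl <- withr::with_seed(31, random_seq(300))
  reads <- rep(tpl, 100)
  rec <- data.frame(clone_id = "c.1", gene = "g", sequence = tpl,
                    support = 100L, tolerance = 0.05, polish_iters = 0L,
                    converged = NA, status = "ok", reason = "",
                    stringsAsFactors = FALSE)
  out <- polish(rec, reads)
  expect_identical(out$sequence, tpl)
  expect_equal(out$polish_iters, 1L)
  expect_true(out$converged)

  # one substitution corrected in a single iteration
  bad <- tpl
  substr(bad, 150, 150) <- if (substr(tpl, 150, 150) == "A") "C" else "A"
  rec$sequence <- bad
  out2 <- polish(rec, reads)
  expect_identical(out2$sequence, tpl)

  expect_error(polish(transform(rec, status = "failed"), reads), "ok")
})

test_that("polishing never drifts away from the true template", {
  tpl <- withr::with_seed(37, random_seq(363))
  for (s in 1:3) {
    rr <- simulate_reads(tpl, 150, error_model(), rng_seed = 100 + s)
    cl <- make_cluster(oriented_reads(rr))
    recs <- build_consensus(cl, min_support = 20)
    d0 <- as.integer(adist(recs$sequence[1], tpl))
    parts <- attr(recs, "partitions")
    sup <- cl$seq[match(parts[[recs$clone_id[1]]], cl$read_id)]
    out <- polish(recs[1, ], sup)
    d1 <- as.integer(adist(out$sequence, tpl))
    expect_lte(d1, d0)
  }
})

test_that("two clones sharing a V gene are split before assembly", {
  db <- test_db()
  vg <- db_genes(db, "V"); dg <- db_genes(db, "D"); jg <- db_genes(db, "J")
  # same V, strongly divergent junctions
  spA <- clone_spec(vg$name[2], dg$name[1], jg$name[1], n1 = "ACG", n2 = "TT",
                    abundance = 0.5)
  spB <- clone_spec(vg$name[2], dg$name[3], jg$name[1],
                    n1 = "GTACCGTTAAGCTTGGA", n2 = "CCATGAATTGCG",
                    j_trim = 10, abundance = 0.5)
  sam <- simulate_sample(db, list(spA, spB), 400, error_model(), rng_seed = 51)
  ids <- sam$read_map$clone_id
  cl <- make_cluster(oriented_reads(sam$reads), gene = vg$name[2],
                     ids = sam$read_map$read_id)
  recs <- build_consensus(cl, min_support = 20)
  expect_equal(sum(recs$status == "ok"), 2)
  parts <- attr(recs, "partitions")
  # partition labels agree with simulator truth >= 90%
  for (cid in names(parts)) {
    members <- ids[match(parts[[cid]], sam$read_map$read_id)]
    expect_gte(max(table(members)) / length(members), 0.9)
  }
})
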