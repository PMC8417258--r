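test_that("recombination assembles V + N1 + D + N2 + J with exact layout", {
  db <- test_db()
  vg <- db_genes(db, "V"); dg <- db_genes(db, "D"); jg <- db_genes(db, "J")

  # identity case: no trims, no N-additions
  sp <- clone_spec(vg$name[1], dg$name[1], jg$name[1])
  rr <- recombine(db, sp, 1)
  expect_identical(rr$seq, paste0(vg$sequence[1], dg$sequence[1],
                                  jg$sequence[1]))

  # fixture V(295) + n1(3) + D(15) + n2(2) + J(48 after j_trim 2) -> 363
  sp2 <- clone_spec(vg$name[1], dg$name[1], jg$name[1],
                    n1 = "ACG", n2 = "TT", j_trim = 2)
  rr2 <- recombine(db, sp2, 1)
  expect_equal(nchar(rr2$seq), 295 + 3 + 15 + 2 + 48)
  expect_equal(rr2$meta$v_span, c(0L, 295L))
  expect_equal(rr2$meta$j_start0, 315L)

  # invariant violations
  expect_error(recombine(db, clone_spec(vg$name[1], dg$name[1], jg$name[1],
                                        v_trim = 295), 1), "v_trim")
  expect_error(recombine(db, clone_spec("IGHV9-99", dg$name[1], jg$name[1]), 1),
               "unknown gene")

  # forced unproductive junctions really are unproductive
  spu <- clone_spec(vg$name[1], dg$name[1], jg$name[1],
                    force_unproductive = TRUE)
  expect_false(recombine(db, spu, 1)$meta$productive)
})

test_that("SHM is substitution-only, span-confined, Binomial in count", {
  db <- test_db()
  seq <- db_genes(db, "V")$sequence[1]

  m0 <- apply_shm(seq, c(0, 295), 0, rng_seed = 5)
  expect_identical(m0$seq, seq)
  expect_length(m0$positions, 0)

  # rate 1 on a 10-nt span: every position mutated, none to the same base
  m1 <- apply_shm(seq, c(10, 20), 1, rng_seed = 5)
  expect_equal(m1$positions, 10:19)
  orig <- strsplit(seq, "")[[1]]; mut <- strsplit(m1$seq, "")[[1]]
  expect_true(all(orig[11:20] != mut[11:20]))
  expect_identical(orig[-(11:20)], mut[-(11:20)])
  expect_equal(nchar(m1$seq), nchar(seq))

  # mutation count equals an independent Bernoulli re-draw on the same stream
  m <- apply_shm(seq, c(0, 295), 0.03, rng_seed = 42)
  oracle_n <- withr::with_seed(42, sum(runif(295) < 0.03))
  expect_equal(length(m$positions), oracle_n)
})

test_that("read simulation realizes the requested error model", {
  template <- withr::with_seed(1, random_seq(363))

  zero <- error_model(0, 0, 0)
  r0 <- simulate_reads(template, 200, zero, rng_seed = 3)
  expect_equal(nrow(r0), 200)
  expect_true(all(nchar(r0$seq) == nchar(template)))
  oriented <- oriented_reads(r0)
  expect_true(all(oriented == template))
  # both strands actually used
  expect_gt(sum(r0$revcomp), 50)
  expect_gt(sum(!r0$revcomp), 50)

  # mean normalized edit distance ~ total error rate (oracle: direct edit
  # distance over the emitted reads); >1e5 simulated bases
  em <- error_model(0.03, 0.03, 0.04)
  rr <- simulate_reads(template, 2000, em, rng_seed = 7)
  d <- as.integer(adist(oriented_reads(rr), template))
  expect_lt(abs(mean(d) / nchar(template) - 0.10), 0.01)

  # determinism
  expect_identical(simulate_reads(template, 50, em, rng_seed = 11),
                   simulate_reads(template, 50, em, rng_seed = 11))
})

test_that("sample simulation apportions reads and records coherent truth", {
  db <- test_db()
  sp1 <- productive_spec(db, v_idx = 1, abundance = 0.7)
  sp2 <- productive_spec(db, v_idx = 5, abundance = 0.3)
  sam <- simulate_sample(db, list(sp1, sp2), 1000, error_model(),
                         rng_seed = 3)
  expect_equal(sam$clones$n_reads, c(700, 300))
  expect_equal(nrow(sam$reads), 1000)
  expect_equal(as.integer(table(sam$read_map$clone_id)[c("clone01", "clone02")]),
               c(700L, 300L))

  # one clone, abundance 1: all reads mapped to it
  one <- simulate_sample(db, list(productive_spec(db)), 100, error_model(),
                         rng_seed = 4)
  expect_true(all(one$read_map$clone_id == "clone01"))
  expect_equal(nrow(one$read_map), 100)

  expect_error(
    simulate_sample(db, list(productive_spec(db, abundance = 0.6),
                             productive_spec(db, v_idx = 2, abundance = 0.3)),
                    100, error_model(), rng_seed = 1),
    "sum to 1")

  # whole sample byte-reproducible for a fixed seed
  sam2 <- simulate_sample(db, list(sp1, sp2), 1000, error_model(),
                          rng_seed = 3)
  expect_identical(sam$reads, sam2$reads)
  expect_identical(sam$clones, sam2$clones)
})

test_that("truth identity is recomputable from the recorded mutations", {
  db <- test_db()
  for (rate in c(0, 0.02, 0.05)) {
    sp <- productive_spec(db, v_idx = 2, shm_rate = rate)
    sam <- simulate_sample(db, list(sp), 5, error_model(0, 0, 0),
                           rng_seed = 17)
    cl <- sam$clones
    pos <- if (nzchar(cl$mut_positions)) {
      as.integer(strsplit(cl$mut_positions, ",")[[1]])
    } else integer(0)
    expect_equal(cl$n_mut, length(pos))
    expect_true(all(pos >= 0 & pos < cl$v_len))
    expect_equal(cl$v_identity_true, 100 * (1 - length(pos) / cl$v_len))
  }
})
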