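# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

test_db <- function() {
  if (is.null(.fixture_cache$db)) {
    .fixture_cache$db <- build_fixture_db(8, seed = 42)
  }
  .fixture_cache$db
}

# index-based convenience over productive_clone_spec()
productive_spec <- function(db = test_db(), v_idx = 1, shm_rate = 0,
                            abundance = 1, d_idx = 1,
                            force_unproductive = FALSE, shm_exact = FALSE) {
  vg <- db_genes(db, "V"); dg <- db_genes(db, "D"); jg <- db_genes(db, "J")
  productive_clone_spec(db, vg$name[v_idx], dg$name[d_idx], jg$name[1],
                        shm_rate = shm_rate, shm_exact = shm_exact,
                        abundance = abundance,
                        force_unproductive = force_unproductive)
}

# Pure-R brute-force Smith-Waterman with affine gaps (gap length L costs
# open + L * ext); the independent oracle for the aligner.
sw_oracle_score <- function(q, r, match = 2, mism = -4, open = -4, ext = -2) {
  n <- nchar(q); m <- nchar(r)
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  FF <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] + open + ext, E[i, j - 1] + ext)
      FF[i, j] <- max(H[i - 1, j] + open + ext, FF[i - 1, j] + ext)
      s <- if (qc[i - 1] == rc[j - 1]) match else mism
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], FF[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# read_cluster built directly from oriented sequences (bypasses stage 1)
make_cluster <- function(seqs, gene = "IGHV1-1",
                         ids = sprintf("r%05d", seq_along(seqs))) {
  structure(list(gene = gene, read_id = ids, seq = seqs, n = length(seqs)),
            class = "read_cluster")
}

# orient simulated reads using simulator truth (for consensus-only tests)
oriented_reads <- function(sim_reads) {
  s <- sim_reads$seq
  s[sim_reads$revcomp] <- revcomp(s[sim_reads$revcomp])
  s
}
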