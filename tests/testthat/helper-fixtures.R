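# shared fixture builders for the suite (all built in code, no data files)

# a deep concentric stack: positions 1..n_pairs and (2*n_pairs+n_loop) down
# pair up, the middle stays unpaired — handy for reactivity statistics
big_paired_structure <- function(n_pairs = 2500L, n_loop = 5000L) {
  n <- 2L * n_pairs + n_loop
  secondary_structure(n, cbind(seq_len(n_pairs), n + 1L - seq_len(n_pairs)))
}

# a tiny transcript: two GUGAG hairpins and two CUCAC repeats far downstream
# (all other bases A so no accidental complements exist)
two_loop_toy <- function() {
  n <- 200L
  bases <- rep("A", n)
  st1 <- list(s5 = 1L, e5 = 5L, s3 = 15L, e3 = 19L)   # loop 6..14
  st2 <- list(s5 = 25L, e5 = 29L, s3 = 39L, e3 = 43L) # loop 30..38
  for (s in list(st1, st2)) {
    bases[s$s5:s$e5] <- c("G", "G", "G", "G", "G")
    bases[s$s3:s$e3] <- c("C", "C", "C", "C", "C")
  }
  bases[7:11] <- c("G", "U", "G", "A", "G")
  bases[31:35] <- c("G", "U", "G", "A", "G")
  bases[150:154] <- c("C", "U", "C", "A", "C")
  bases[160:164] <- c("C", "U", "C", "A", "C")
  prs <- rbind(cbind(1:5, 19:15), cbind(25:29, 43:39))
  list(sequence = paste(bases, collapse = ""),
       structure = secondary_structure(n, prs))
}

expect_same_registers <- function(got, want) {
  expect_setequal(paste(got$loop_start, got$repeat_start),
                  paste(want$loop_start, want$repeat_start))
}
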