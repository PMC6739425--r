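test_that("hairpin loops are the unpaired runs under innermost pairs", {
  l1 <- hairpin_loops(parse_dotbracket("(((...)))"))
  expect_identical(nrow(l1), 1L)
  expect_identical(c(l1$start, l1$end), c(4L, 6L))

  l2 <- hairpin_loops(parse_dotbracket("((..))((...))"))
  expect_identical(nrow(l2), 2L)

  l0 <- hairpin_loops(parse_dotbracket("........."))
  expect_identical(nrow(l0), 0L)
})

test_that("the scanner finds exactly the planted registers in the core", {
  core <- gen_core(core_layout(), seed = 1)
  reg <- scan_kissing(core$sequence, core$structure, scan_params())
  expect_identical(nrow(reg), 6L)
  expect_identical(reg$label, paste0("TR", 1:6))
  expect_same_registers(reg, core$registers)
  # registers are ordered 5' to 3' along the repeat region
  expect_true(all(diff(reg$repeat_start) > 0))
  # default wobble plan: 4 WC + 1 G-U per register, one exclusivity group
  expect_true(all(reg$n_wc == 4L & reg$n_wobble == 1L))
  expect_identical(unique(reg$group), 1L)
})

test_that("paired candidates are rejected unless violations are allowed", {
  core <- gen_core(core_layout(), seed = 1)
  # pair up the repeat region in an alternative structure
  extra <- cbind(290:319, 355:326)
  st2 <- secondary_structure(core$structure$length,
                             rbind(as.matrix(core$structure$pairs[, c("i", "j")]),
                                   extra))
  reg <- scan_kissing(core$sequence, st2, scan_params())
  expect_identical(nrow(reg), 0L)
  # relaxing single-strandedness readmits the planted repeats (other paired
  # windows may now qualify too; only the planted recovery is guaranteed)
  reg2 <- scan_kissing(core$sequence, st2,
                       scan_params(max_unpaired_violations = 5L))
  expect_true(all(paste(core$registers$loop_start,
                        core$registers$repeat_start) %in%
                    paste(reg2$loop_start, reg2$repeat_start)))
})

test_that("wobble handling distinguishes CUCAC from CUCAU partners", {
  make_toy <- function(repeat_seq) {
    n <- 40L
    bases <- rep("A", n)
    bases[1:5] <- "G"; bases[15:19] <- "C"
    bases[7:11] <- c("G", "U", "G", "A", "G")
    bases[30:34] <- strsplit(repeat_seq, "")[[1]]
    list(sequence = paste(bases, collapse = ""),
         structure = secondary_structure(n, cbind(1:5, 19:15)))
  }
  prm <- scan_params(min_distance = 5L)
  wc <- make_toy("CUCAC")
  reg <- scan_kissing(wc$sequence, wc$structure, prm)
  expect_identical(nrow(reg), 1L)
  expect_identical(reg$n_wc, 5L)
  expect_identical(reg$n_wobble, 0L)

  wob <- make_toy("CUCAU")
  regw <- scan_kissing(wob$sequence, wob$structure, prm)
  expect_identical(nrow(regw), 1L)
  expect_identical(regw$n_wc, 4L)
  expect_identical(regw$n_wobble, 1L)
  # wobble disabled: no register at all
  regn <- scan_kissing(wob$sequence, wob$structure,
                       scan_params(min_distance = 5L, allow_wobble = FALSE))
  expect_identical(nrow(regn), 0L)
})

test_that("registers group by shared loop positions only", {
  toy <- two_loop_toy()
  reg <- scan_kissing(toy$sequence, toy$structure,
                      scan_params(min_distance = 80L))
  expect_identical(nrow(reg), 4L)
  expect_identical(length(unique(reg$group)), 2L)
  for (g in unique(reg$group)) {
    rows <- reg[reg$group == g, ]
    # within a group every pair of registers overlaps on the loop
    if (nrow(rows) > 1)
      for (a in 1:(nrow(rows) - 1)) for (b in (a + 1):nrow(rows))
        expect_true(rows$loop_start[a] <= rows$loop_end[b] &&
                      rows$loop_start[b] <= rows$loop_end[a])
  }
  across <- expand.grid(a = which(reg$group == 1), b = which(reg$group == 2))
  for (r in seq_len(nrow(across)))
    expect_false(reg$loop_start[across$a[r]] <= reg$loop_end[across$b[r]] &&
                   reg$loop_start[across$b[r]] <= reg$loop_end[across$a[r]])
})

test_that("loops shorter than the motif are skipped with a notice", {
  st <- parse_dotbracket("((((...))))")
  expect_message(reg <- scan_kissing("GGGGAAACCCC", st, scan_params()),
                 "shorter than k")
  expect_identical(nrow(reg), 0L)
})

test_that("compensatory design restores Watson-Crick pairing", {
  core <- gen_core(core_layout(), seed = 1)
  reg <- scan_kissing(core$sequence, core$structure, scan_params())
  # the central G of the motif faces a U (wobble); G->C rescues with U->G
  panel <- design_rescue_panel(reg, position = 80L, from = "G", to = "C",
                               sequence = core$sequence)
  expect_identical(nrow(panel), 6L)
  expect_true(all(panel$repeat_from == "U"))
  expect_true(all(panel$repeat_to == "G"))
  expect_identical(length(unique(panel$repeat_position)), 6L)

  # loop A paired to U: the rescue is U->A
  d <- design_compensatory(reg, 1L, position = 81L, from = "A", to = "U")
  expect_identical(d$to, "A")
  expect_error(design_compensatory(reg, 1L, position = 200L, "A", "U"),
               "not inside")
})

test_that("every double mutant restores its register when re-scanned", {
  core <- gen_core(core_layout(), seed = 1)
  reg <- scan_kissing(core$sequence, core$structure, scan_params())
  panel <- design_rescue_panel(reg, position = 80L, from = "G", to = "C",
                               sequence = core$sequence)
  k <- 5L
  for (r in seq_len(nrow(panel))) {
    bases <- strsplit(core$sequence, "")[[1]]
    bases[panel$loop_position[r]] <- panel$loop_to[r]
    bases[panel$repeat_position[r]] <- panel$repeat_to[r]
    mut <- paste(bases, collapse = "")
    re <- scan_kissing(mut, core$structure, scan_params())
    row <- re[re$loop_start == reg$loop_start[r] &
                re$repeat_start == reg$repeat_start[r], ]
    expect_identical(nrow(row), 1L)
    expect_identical(row$n_wc + row$n_wobble, k)
  }
})

test_that("repeat conservation counts match a brute-force search", {
  core <- gen_core(core_layout(), seed = 3)
  aln <- simulate_alignment(core, n_species = 12, seed = 4)
  rc <- repeat_conservation(aln)
  # independent naive scan: reverse-complement string matching with wobble
  naive_count <- function(row, motif = "GUGAG") {
    b <- strsplit(gsub("-", "", row), "")[[1]]
    mb <- strsplit(motif, "")[[1]]
    pairs_ok <- function(x, y)
      (x == "A" & y == "U") | (x == "U" & y == "A") |
      (x == "G" & y == "C") | (x == "C" & y == "G") |
      (x == "G" & y == "U") | (x == "U" & y == "G")
    hits <- 0
    for (p in seq_len(length(b) - 4)) {
      cand <- rev(b[p:(p + 4)])
      if (all(pairs_ok(mb, cand))) hits <- hits + 1
    }
    hits
  }
  expect_identical(rc$count,
                   vapply(aln$sequences, naive_count, numeric(1),
                          USE.NAMES = FALSE) |> as.integer())
  # a row with no complement at all
  aln2 <- list(sequences = c(dead = paste(rep("A", 60), collapse = "")))
  rc2 <- repeat_conservation(aln2)
  expect_identical(rc2$count, 0L)
  expect_false(rc2$pass)
  expect_error(repeat_conservation(list(sequences = character())), "empty")
})

test_that("covariation scores reflect planted compensatory substitutions", {
  # hand-built alignment: columns 1 and 9 pair; two rows co-substitute
  rows <- c(a = "GAAAAAAAC", b = "GAAAAAAAC", c = "GAAAAAAAC",
            d = "CAAAAAAAG", e = "CAAAAAAAG", f = "AAAAAAAAA")
  cv <- covariation(list(sequences = rows), pairs = cbind(1, 9),
                    n_perm = 20, seed = 1)
  expect_equal(cv$fraction_canonical, 5 / 6)
  expect_identical(cv$n_compensatory, 2L)
  expect_equal(cv$score, 5 / 6 + 2 * 2 / 6)

  # invariant canonical columns: no compensatory evidence
  inv <- covariation(list(sequences = rows[1:3]), pairs = cbind(1, 9),
                     n_perm = 10, seed = 2)
  expect_identical(inv$n_compensatory, 0L)
  expect_equal(inv$fraction_canonical, 1)

  # row order must not matter
  cv2 <- covariation(list(sequences = rev(rows)), pairs = cbind(1, 9),
                     n_perm = 20, seed = 1)
  expect_equal(cv2$score, cv$score)

  # alignment-wide gap column insertion shifts indices, not scores
  rows_g <- sub("^(....)", "\\1-", rows)
  cv3 <- covariation(list(sequences = rows_g), pairs = cbind(1, 10),
                     n_perm = 20, seed = 1)
  expect_equal(cv3$score, cv$score)
})

test_that("column shuffling destroys covariation significance", {
  core <- gen_core(core_layout(), seed = 5)
  aln <- simulate_alignment(core, n_species = 30, seed = 6)
  pr <- attr(aln, "planted_pairs")[1, ]
  rows <- do.call(rbind, strsplit(aln$sequences, ""))
  set.seed(7)
  nonsig <- 0L
  for (rep in 1:100) {
    shuf <- rows
    shuf[, pr$i] <- sample(shuf[, pr$i])
    shuf[, pr$j] <- sample(shuf[, pr$j])
    null_aln <- list(sequences = apply(shuf, 1, paste, collapse = ""))
    names(null_aln$sequences) <- names(aln$sequences)
    cv <- covariation(null_aln, pairs = cbind(pr$i, pr$j),
                      n_perm = 40, seed = rep)
    if (cv$evalue > 0.05) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 95L)
})

test_that("a register annotates onto the pseudoknot layer", {
  core <- gen_core(core_layout(), seed = 1)
  reg <- scan_kissing(core$sequence, core$structure, scan_params())
  st <- annotate_pseudoknot(core$structure, reg, which = 3)
  expect_identical(sum(st$pairs$layer == "pseudoknot"), 5L)
  db <- write_dotbracket(st)
  expect_true(grepl("\\[", db) && grepl("\\]", db))
  expect_identical(parse_dotbracket(db)$pt, st$pt)
})
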