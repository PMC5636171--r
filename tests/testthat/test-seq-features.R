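test_that("Markov model training matches hand-computed smoothed counts", {
  # two 3-mers: ACG, ACT; alpha = 0.5
  m <- train_markov_3ss(c("ACG", "ACT"), pseudocount = 0.5)
  expect_equal(m$W, 3)
  # initial: A seen twice -> (2 + .5) / (2 + 2) = 0.625
  expect_equal(unname(m$initial["A"]), 2.5 / 4)
  expect_equal(unname(m$initial["C"]), 0.5 / 4)
  # position 2, prev A: C seen twice -> (2 + .5) / (2 + 2)
  expect_equal(m$trans[[2]]["A", "C"], 2.5 / 4)
  expect_equal(m$trans[[2]]["G", "C"], 0.5 / 2)
  # position 3, prev C: G once, T once -> (1 + .5) / (2 + 2)
  expect_equal(m$trans[[3]]["C", "G"], 1.5 / 4)
  expect_equal(m$trans[[3]]["C", "T"], 1.5 / 4)
  # every conditional distribution sums to one
  for (i in 2:3) expect_equal(unname(rowSums(m$trans[[i]])), rep(1, 4))
  expect_warning(train_markov_3ss(c("ACG", "ACGT", "ANG"), 0.5), "rejected")
  expect_error(suppressWarnings(train_markov_3ss(c("ANG"), 0.5)), "no usable")
})

test_that("model probabilities normalize exhaustively at reduced window", {
  set.seed(5)
  m <- train_markov_3ss(random_acgt(40, 5), pseudocount = 0.5)
  bases <- c("A", "C", "G", "T")
  all5 <- apply(expand.grid(rep(list(bases), 5)), 1, paste, collapse = "")
  total <- sum(2^markov_log2_prob(m, all5))
  expect_equal(total, 1, tolerance = 1e-9)
})

test_that("scores are zero under identical models and antisymmetric under swap", {
  set.seed(6)
  fg <- train_markov_3ss(random_acgt(30, 8))
  bg <- train_markov_3ss(random_acgt(30, 8))
  probes <- random_acgt(20, 8)
  expect_equal(score_3ss(probes, fg, fg), rep(0, 20), tolerance = 1e-12)
  expect_equal(score_3ss(probes, fg, bg), -score_3ss(probes, bg, fg),
               tolerance = 1e-12)
})

test_that("sequences sampled from the foreground outscore background samples", {
  set.seed(8)
  # biased foreground (pyrimidine-rich) vs uniform background
  fg_train <- vapply(1:300, function(i)
    paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE,
                 prob = c(.08, .36, .07, .49)), collapse = ""), "")
  fg <- train_markov_3ss(fg_train)
  bg <- train_markov_3ss(random_acgt(300, 10))
  s_fg <- score_3ss(sample_markov_3ss(fg, 500), fg, bg)
  s_bg <- score_3ss(sample_markov_3ss(bg, 500), fg, bg)
  expect_gt(mean(s_fg), mean(s_bg))
})

test_that("training recovers the conditional probabilities of a known generator", {
  set.seed(9)
  gen <- train_markov_3ss(random_acgt(25, 6), pseudocount = 0.5)
  draws <- sample_markov_3ss(gen, 10000)
  fit <- train_markov_3ss(draws, pseudocount = 0.5)
  expect_equal(unname(fit$initial), unname(gen$initial), tolerance = 0.02)
  # per-cell error scales with how often each conditioning context is
  # visited, so compare cells occupancy-weighted: the weighted mean absolute
  # error must be below 0.02 and well-sampled cells individually below 0.05
  mat <- do.call(rbind, strsplit(draws, ""))
  for (i in 2:6) {
    occ <- table(factor(mat[, i - 1], levels = c("A", "C", "G", "T")))
    err <- abs(fit$trans[[i]] - gen$trans[[i]])
    wmae <- sum(err * as.numeric(occ)) / (4 * sum(occ))
    expect_lt(wmae, 0.02)
    expect_true(all(err[occ >= 500, ] < 0.05))
  }
})

test_that("score-set comparison reports means, difference, and the gated test", {
  set.seed(10)
  a <- rnorm(101, 7.6, 2)
  res <- compare_score_sets(a, a)
  expect_equal(res$difference, 0)
  expect_gt(res$p_value, 0.9)
  b <- rnorm(252, 8.9, 2)
  res <- compare_score_sets(a, b)
  expect_equal(res$difference, mean(a) - mean(b))
  expect_true(res$test_name %in% c("t-test", "mann-whitney"))
})

test_that("GC differential counts G+C excluding N", {
  expect_equal(gc_differential("GGCC", "ATAT"), 100)
  expect_equal(gc_differential("GCGC", "GCGC"), 0)
  expect_equal(gc_differential("GCNN", "ATNN"), 100)
  set.seed(12)
  for (i in 1:20) {
    a <- random_acgt(1, 50); b <- random_acgt(1, 60)
    ora <- function(s) {
      ch <- strsplit(s, "")[[1]]
      100 * sum(ch %in% c("G", "C")) / length(ch)
    }
    expect_equal(gc_differential(a, b), ora(a) - ora(b), tolerance = 1e-12)
  }
  expect_error(gc_differential("NNN", "ACGT"), "no non-N")
})

test_that("nearest upstream AG matches a brute-force scan", {
  expect_equal(nearest_upstream_ag("AGTTAG"), 4L)
  expect_identical(nearest_upstream_ag("GTTTTTTTAG"), NA_integer_)
  expect_identical(nearest_upstream_ag("AGT"), NA_integer_)
  expect_warning(nearest_upstream_ag("GTAAAT"), "does not end in AG")
  set.seed(13)
  for (i in 1:1000) {
    s <- paste0(random_acgt(1, sample(4:40, 1)), "AG")
    got <- nearest_upstream_ag(s)
    # brute force: walk upstream from the terminal AG
    n <- nchar(s)
    found <- NA_integer_
    for (p in seq(n - 2, 1)) {
      if (substr(s, p, p + 1) == "AG") { found <- (n - 1L) - p; break }
    }
    expect_identical(got, as.integer(found))
  }
})

test_that("motif scanning agrees with a regex oracle for IUPAC strings", {
  hits <- scan_motifs("GTGT", c(gt = "GT"))
  expect_equal(hits$n_matches, 2)
  expect_equal(hits$positions[[1]], c(1L, 3L))
  hits <- scan_motifs("AAGTAAGCCGTGAG", c(donor = "GTRAG"))
  expect_equal(hits$positions[[1]], c(3L, 10L))
  expect_equal(scan_motifs("AAGTAAGG", c(donor = "GTRAG"))$n_matches, 1)
  # degenerate motif matches both GTAAG and GTGAG
  expect_equal(scan_motifs("GTAAGTTGTGAG", c(d = "GTRAG"))$n_matches, 2)
  iupac_to_regex <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]",
                      Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]",
                      M = "[AC]", B = "[CGT]", D = "[AGT]", H = "[ACT]",
                      V = "[ACG]", N = "[ACGT]")
  set.seed(14)
  motifs <- c("GTRAG", "YAG", "SWN", "TTT")
  for (i in 1:200) {
    s <- random_acgt(1, sample(20:60, 1))
    for (m in motifs) {
      rx <- paste(iupac_to_regex[strsplit(m, "")[[1]]], collapse = "")
      oracle <- length(gregexpr(paste0("(?=", rx, ")"), s, perl = TRUE)[[1]])
      if (gregexpr(paste0("(?=", rx, ")"), s, perl = TRUE)[[1]][1] == -1) oracle <- 0
      expect_equal(scan_motifs(s, m)$n_matches, oracle)
    }
  }
  expect_warning(scan_motifs("ACGT", c(bad = "Q!")), "malformed motif")
})

test_that("PWM scanning respects an absolute log-odds threshold", {
  pwm <- matrix(log2(c(0.97, 0.01, 0.01, 0.01,
                       0.01, 0.01, 0.97, 0.01) / 0.25),
                nrow = 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  hits <- scan_motifs("TTAGTT", list(ag = pwm), pwm_min_score = 3.0)
  expect_equal(hits$positions[[1]], 3L)
  expect_equal(scan_motifs("TTTTTT", list(ag = pwm), pwm_min_score = 3.0)$n_matches, 0)
})

test_that("alternate 5'SS detection is the GTRAG motif scan", {
  expect_equal(detect_alt_5ss("AAGTGAGAA"), 3L)
  expect_length(detect_alt_5ss("ACCCCCA"), 0)
  set.seed(15)
  for (i in 1:50) {
    s <- random_acgt(1, 60)
    expect_equal(detect_alt_5ss(s), sort(scan_motifs(s, "GTRAG")$positions[[1]]))
  }
})

test_that("planted weak acceptor windows score lower than strong ones", {
  cfg <- sim_config(n_genes = 40, fraction_responsive = 0.5, seed = 21)
  sim <- generate_genome_annotation(cfg)
  windows <- vapply(sim$events, `[[`, "", "ss3_window")
  weak_ids <- sim$truth$event_id[sim$truth$weak_3ss]
  strong_ids <- sim$truth$event_id[!sim$truth$weak_3ss]
  fg <- train_markov_3ss(unname(windows[strong_ids]))
  bg <- train_markov_3ss(sim$ss3_background)
  expect_lt(mean(score_3ss(unname(windows[weak_ids]), fg, bg)),
            mean(score_3ss(unname(windows[strong_ids]), fg, bg)))
})
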