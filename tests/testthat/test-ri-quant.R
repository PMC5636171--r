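test_that("effective lengths follow the read-start counting formula", {
  L <- effective_lengths(100, 100, 8)
  expect_equal(unname(L["L_inc"]), 185)
  expect_equal(unname(L["L_exc"]), 85)
  # algebraic identity across geometries
  for (il in c(1, 50, 500)) for (rl in c(50, 100)) for (ov in c(4, 8)) {
    L <- effective_lengths(il, rl, ov)
    expect_equal(unname(L["L_inc"] - L["L_exc"]), il)
  }
  expect_error(effective_lengths(100, 16, 8), "read_length")
  expect_error(effective_lengths(0, 100, 8), "intron_length")
})

test_that("replicate pooling is additive, order-invariant, and checks lengths", {
  counts <- rbind(
    make_counts_row(sample_id = "r1", I_body = 10L, I_junc5 = 0L, I_junc3 = 0L, E = 5L),
    make_counts_row(sample_id = "r2", I_body = 20L, I_junc5 = 0L, I_junc3 = 0L, E = 15L)
  )
  pooled <- pool_replicates(counts, "normoxia")
  expect_equal(pooled$I_body, 30L)
  expect_equal(pooled$E, 20L)
  expect_equal(pooled$L_inc, 185)
  # order invariance
  pooled_rev <- pool_replicates(counts[2:1, ], "normoxia")
  expect_equal(pooled[names(pooled_rev)], pooled_rev)
  # single replicate is the identity on counts
  one <- pool_replicates(counts[1, ], "normoxia")
  expect_equal(one$I_body, 10L)
  # inconsistent annotation is an error
  bad <- counts
  bad$L_inc[2] <- 300
  expect_error(pool_replicates(bad, "normoxia"), "inconsistent effective lengths")
  expect_error(pool_replicates(counts, "hypoxia"), "no replicates")
})

test_that("Psi posterior handles pure-inclusion, symmetric and length-weighted cases", {
  # pure inclusion
  post <- estimate_psi(pooled_event(I = 50L, E = 0L))
  expect_equal(post$map, 1)
  expect_equal(post$psi_hat, 1)
  # symmetry at equal effective lengths
  post <- estimate_psi(pooled_event(I = 40L, E = 40L, L_inc = 85, L_exc = 85))
  expect_equal(post$psi_hat, 0.5)
  expect_equal(post$mean, 0.5, tolerance = 1e-9)
  expect_equal(rev(post$mass), post$mass, tolerance = 1e-12)
  # length weighting: I=80, E=20, L_inc=400, L_exc=100 -> psi_hat = 0.5
  post <- estimate_psi(pooled_event(I = 80L, E = 20L, L_inc = 400, L_exc = 100))
  expect_equal(post$psi_hat, 0.5)
  expect_equal(post$mean, oracle_psi_mean(80, 20, 400, 100), tolerance = 1e-3)
  expect_error(estimate_psi(pooled_event(I = 0L, E = 0L)), "undefined posterior")
})

test_that("posterior mass normalizes, CI contains the mean, and mean is monotone in I", {
  set.seed(7)
  means <- numeric(0)
  for (I in c(0L, 5L, 20L, 60L, 120L)) {
    post <- estimate_psi(pooled_event(I = I, E = 30L))
    expect_equal(sum(post$mass), 1, tolerance = 1e-9)
    expect_true(post$ci95[1] <= post$mean && post$mean <= post$ci95[2])
    means <- c(means, post$mean)
  }
  expect_true(all(diff(means) > 0))
})

test_that("Bayes factor favors shared Psi for exchangeable data and separates extremes", {
  a <- pooled_event(I = 50L, E = 50L)
  res <- delta_psi_bayes_factor(a, a)
  expect_lt(res$bayes_factor, 1)
  expect_false(res$significant)
  b1 <- pooled_event(I = 100L, E = 0L, L_inc = 85, L_exc = 85)
  b2 <- pooled_event(I = 0L, E = 100L, L_inc = 85, L_exc = 85)
  res <- delta_psi_bayes_factor(b1, b2)
  expect_gte(res$bayes_factor, 20)
  expect_gt(abs(res$delta_psi), 0.9)
  expect_true(res$significant)
})

test_that("grid Bayes factors and means agree with the fine-grid quadrature oracle", {
  set.seed(11)
  for (i in 1:8) {
    Ia <- rpois(1, 60); Ea <- rpois(1, 40)
    Ib <- rpois(1, 30); Eb <- rpois(1, 70)
    if (Ia + Ea == 0 || Ib + Eb == 0) next
    res <- delta_psi_bayes_factor(pooled_event(I = Ia, E = Ea),
                                  pooled_event(I = Ib, E = Eb))
    lo <- oracle_log_bf(Ia, Ea, Ib, Eb, 185, 85)
    expect_equal(res$log10_bf * log(10), lo, tolerance = 0.02 * max(1, abs(lo)))
    expect_equal(res$posterior_a$mean, oracle_psi_mean(Ia, Ea, 185, 85),
                 tolerance = 1e-3)
  }
})

test_that("swapping condition labels negates delta-Psi and keeps the Bayes factor", {
  a <- pooled_event(I = 70L, E = 30L)
  b <- pooled_event(I = 20L, E = 90L)
  res_ab <- delta_psi_bayes_factor(a, b)
  res_ba <- delta_psi_bayes_factor(b, a)
  expect_equal(res_ab$delta_psi, -res_ba$delta_psi, tolerance = 1e-12)
  expect_equal(res_ab$log10_bf, res_ba$log10_bf, tolerance = 1e-9)
})

test_that("detection filter applies the 20-read rule per condition and is monotone", {
  counts <- rbind(
    make_counts_row("ev_low", "n1", "normoxia", I_body = 10L, I_junc5 = 2L,
                    I_junc3 = 2L, E = 5L),                       # 19 reads
    make_counts_row("ev_low", "h1", "hypoxia", I_body = 30L, E = 30L),
    make_counts_row("ev_ok", "n1", "normoxia", I_body = 10L, I_junc5 = 3L,
                    I_junc3 = 2L, E = 5L),                       # 20 reads
    make_counts_row("ev_ok", "h1", "hypoxia", I_body = 10L, E = 10L)
  )
  expect_equal(apply_detection_filter(counts, 20L), "ev_ok")
  expect_setequal(apply_detection_filter(counts, 0L), c("ev_low", "ev_ok"))
  # raising the threshold never adds events
  prev <- apply_detection_filter(counts, 0L)
  for (m in c(5L, 19L, 20L, 21L, 100L)) {
    cur <- apply_detection_filter(counts, m)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("direction fraction counts positive significant events", {
  res <- data.frame(event_id = paste0("e", 1:12),
                    delta_psi = c(rep(0.3, 9), -0.3, 0.2, -0.2),
                    significant = c(rep(TRUE, 10), FALSE, FALSE))
  d <- direction_fraction(res)
  expect_equal(d$fraction, 0.9)
  expect_equal(d$n_significant, 10)
  res$significant <- FALSE
  expect_error(direction_fraction(res), "no significant events")
})

test_that("event-type enrichment matches the proportion-test construction", {
  tab <- data.frame(category = c("RI", "SE", "A3SS"),
                    n_detected = c(100L, 1000L, 500L),
                    n_significant = c(90L, 100L, 50L))
  enr <- event_type_enrichment(tab)
  expect_equal(nrow(enr), 3)
  expect_lt(enr$p_value[enr$category == "RI"], 0.001)
  # null category: same proportion as the rest
  tab_null <- data.frame(category = c("RI", "SE"),
                         n_detected = c(100L, 1000L),
                         n_significant = c(50L, 500L))
  enr_null <- event_type_enrichment(tab_null)
  expect_gte(min(enr_null$p_value), 0.9)
  # matches independent prop.test on the same 2x2 contrast
  pt <- suppressWarnings(stats::prop.test(c(90, 150), c(100, 1500)))
  expect_equal(enr$p_value[enr$category == "RI"], pt$p.value, tolerance = 1e-12)
  expect_warning(event_type_enrichment(
    data.frame(category = c("RI", "SE", "MXE"), n_detected = c(10L, 50L, 0L),
               n_significant = c(1L, 5L, 0L))), "zero detected")
})
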