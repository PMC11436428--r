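test_that("ROC curve has correct endpoints and counting-based operating points", {
  scores <- c(3, 4, 1, 2)
  labels <- c(1, 1, 0, 0)
  curve <- roc_curve(scores, labels)
  expect_equal(curve$n_pos, 2L)
  expect_equal(curve$n_neg, 2L)
  # endpoints (sens, spec) = (0, 1) and (1, 0)
  expect_equal(curve$sens[1], 0); expect_equal(curve$spec[1], 1)
  expect_equal(curve$sens[length(curve$sens)], 1)
  expect_equal(curve$spec[length(curve$spec)], 0)
  # perfect separation: a cutoff reaching sens 1 and spec 1
  expect_true(any(curve$sens == 1 & curve$spec == 1))
  # sens non-decreasing as cutoffs descend
  expect_true(all(diff(curve$sens) >= 0))

  # degenerate: all scores equal -> only trivial operating points remain
  deg <- roc_curve(rep(2, 6), c(1, 1, 1, 0, 0, 0))
  fin <- is.finite(deg$cutoffs)
  expect_equal(deg$sens[fin], 1)
  expect_equal(deg$spec[fin], 0)

  # random instance: every operating point equals brute-force counting
  set.seed(14)
  sc <- sample(1:10, 30, replace = TRUE)
  lb <- rbinom(30, 1, 0.5)
  lb[1:2] <- c(0, 1)
  cv <- roc_curve(sc, lb)
  for (i in which(is.finite(cv$cutoffs))) {
    ref <- brute_operating_point(sc, lb, cv$cutoffs[i])
    expect_equal(cv$sens[i], ref$sens)
    expect_equal(cv$spec[i], ref$spec)
  }
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC examples and rank-statistic equivalence", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(c(2, 2), c(1, 0)), 0.5)
  # frozen from the 4-pair enumeration: only (3 > 2) scores, so 1/4
  expect_equal(roc_auc(c(1, 3, 2, 4), c(1, 1, 0, 0)), 0.25)

  set.seed(31)
  for (rep in 1:50) {
    n <- sample(6:60, 1)
    sc <- if (rep %% 2) rnorm(n) else sample(1:5, n, replace = TRUE)
    lb <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(roc_auc(sc, lb), brute_auc(sc, lb), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(32)
  sc <- rnorm(80)
  lb <- c(0, 1, rbinom(78, 1, 0.4))
  a <- roc_auc(sc, lb)
  expect_equal(roc_auc(exp(sc), lb), a, tolerance = 1e-12)
  expect_equal(roc_auc(qnorm(pnorm(sc))^3 + sc, lb), a, tolerance = 1e-12)
})

test_that("Youden cutoff maximizes J with the stated tie-breaks", {
  perfect <- roc_curve(c(3, 4, 1, 2), c(1, 1, 0, 0))
  y <- youden_cutoff(perfect)
  expect_equal(y$youden_j, 1)
  expect_equal(y$sens_star, 1)
  expect_equal(y$spec_star, 1)
  expect_equal(y$cutoff_star, 3)  # higher cutoff preferred among J = 1 ties

  # scores carrying no information: J = 0 at the trivial point
  flat <- roc_curve(rep(c(1, 2), 10), rep(c(0, 1, 1, 0), 5))
  yf <- youden_cutoff(flat)
  expect_equal(yf$youden_j, 0)
})

test_that("DeLong AUC interval behaves symmetrically and flags degeneracy", {
  # symmetric null case: interval symmetric about 0.5
  sc <- c(1, 2, 3, 4, 1, 2, 3, 4)
  lb <- c(0, 0, 0, 0, 1, 1, 1, 1)
  ci <- auc_ci(sc, lb)
  expect_equal(ci$auc, 0.5)
  expect_equal(ci$hi - 0.5, 0.5 - ci$lo)
  expect_true(ci$lo <= ci$auc && ci$auc <= ci$hi)

  # interval widens as n shrinks (nested subsamples, same data)
  set.seed(41)
  pos <- rnorm(120, 1); neg <- rnorm(120)
  width <- function(k) {
    r <- auc_ci(c(pos[1:k], neg[1:k]), rep(c(1, 0), each = k))
    r$hi - r$lo
  }
  expect_lt(width(120), width(30))
  expect_lt(width(30), width(10))

  expect_warning(ci1 <- auc_ci(c(5, 6, 1, 2), c(1, 1, 0, 0)), "degenerate")
  expect_equal(c(ci1$lo, ci1$hi), c(1, 1))
})

test_that("DeLong interval coverage is near nominal in simulation", {
  set.seed(52)
  true_auc <- pnorm(1 / sqrt(2))  # unit-variance Gaussians shifted by 1
  hits <- 0L
  reps <- 800L
  for (r in seq_len(reps)) {
    sc <- c(rnorm(40, 1), rnorm(40))
    lb <- rep(c(1, 0), each = 40)
    ci <- auc_ci(sc, lb)
    if (ci$lo <= true_auc && true_auc <= ci$hi) hits <- hits + 1L
  }
  expect_gt(hits / reps, 0.92)
  expect_lt(hits / reps, 0.98)
})

test_that("DeLong AUC machinery agrees with pROC", {
  set.seed(43)
  sc <- rnorm(60)
  sc2 <- rnorm(60) + sc
  lb <- c(0, 1, rbinom(58, 1, 0.5))
  r1 <- pROC::roc(lb, sc, quiet = TRUE, direction = "<")
  expect_equal(roc_auc(sc, lb), as.numeric(pROC::auc(r1)), tolerance = 1e-12)
  ci <- auc_ci(sc, lb)
  pci <- as.numeric(pROC::ci.auc(r1, method = "delong"))
  expect_equal(c(ci$lo, ci$hi), pci[c(1, 3)], tolerance = 1e-8)
  r2 <- pROC::roc(lb, sc2, quiet = TRUE, direction = "<")
  pt <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  ours <- delong_compare(sc, sc2, lb)
  expect_equal(ours$p, pt$p.value, tolerance = 1e-8)
})

test_that("paired DeLong comparison: identity and rank-invariance give p = 1", {
  set.seed(44)
  sc <- rnorm(50)
  lb <- c(0, 1, rbinom(48, 1, 0.5))
  self <- delong_compare(sc, sc, lb)
  expect_equal(self$delta_auc, 0)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)
  mono <- delong_compare(sc, exp(sc) + 2, lb)
  expect_equal(mono$delta_auc, 0)
  expect_equal(mono$p, 1)
  expect_error(delong_compare(sc, sc[-1], lb), "paired")
})

test_that("DeLong variance is close to a bootstrap estimate", {
  set.seed(45)
  n <- 60
  sc_a <- rnorm(n) + rep(c(1, 0), each = n / 2)
  sc_b <- 0.5 * sc_a + rnorm(n)
  lb <- rep(c(1, 0), each = n / 2)
  ours <- delong_compare(sc_a, sc_b, lb)
  v_ours <- (ours$delta_auc / ours$z)^2
  deltas <- replicate(600, {
    i_pos <- sample(which(lb == 1), replace = TRUE)
    i_neg <- sample(which(lb == 0), replace = TRUE)
    i <- c(i_pos, i_neg)
    roc_auc(sc_a[i], lb[i]) - roc_auc(sc_b[i], lb[i])
  })
  expect_equal(v_ours, var(deltas), tolerance = 0.5)
})

test_that("prevalence-adjusted predictive values follow Bayes' rule", {
  # sens 90.0%, spec 71.43%, prevalence 60%
  pm <- prevalence_metrics(0.90, 0.7143, 0.6)
  expect_equal(round(100 * pm$ppv, 1), 82.5)
  expect_equal(round(100 * pm$npv, 1), 82.6)

  perfect <- prevalence_metrics(1, 1, 0.3)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)
  expect_equal(perfect$accuracy, 1)

  # accuracy at sens 71.8%, spec 83.6%, prevalence 60%
  expect_equal(round(100 * prevalence_metrics(0.718, 0.836, 0.6)$accuracy, 1),
               76.5)

  # identities on random operating points
  set.seed(46)
  for (rep in 1:20) {
    se <- runif(1); sp <- runif(1); pi <- runif(1, 0.05, 0.95)
    pm <- prevalence_metrics(se, sp, pi)
    expect_equal(pm$accuracy, se * pi + sp * (1 - pi))
    expect_equal(pm$ppv * (se * pi + (1 - sp) * (1 - pi)), se * pi)
  }
  # zero denominator yields NA, not an error
  expect_true(is.na(prevalence_metrics(0, 1, 0.6)$ppv))
})

test_that("empirical confusion metrics match brute-force counting", {
  sc <- c(3, 4, 1, 2); lb <- c(1, 1, 0, 0)
  at_mid <- empirical_confusion(sc, lb, 2.5)
  expect_equal(unlist(at_mid), c(sens = 1, spec = 1, ppv = 1, npv = 1,
                                 accuracy = 1))
  high <- empirical_confusion(sc, lb, 99)
  expect_equal(high$sens, 0)
  expect_equal(high$spec, 1)

  set.seed(47)
  sc <- sample(1:8, 40, replace = TRUE)
  lb <- c(0, 1, rbinom(38, 1, 0.5))
  for (cut in c(0, 2.5, 4, 8, 9)) {
    got <- empirical_confusion(sc, lb, cut)
    ref <- brute_confusion(sc, lb, cut)
    expect_equal(got$sens, ref$sens)
    expect_equal(got$spec, ref$spec)
  }
})

test_that("metric evaluation report and DeLong matrix are well-formed", {
  co <- generate_cohort(cohort_spec(n_infected = 60, n_noninfected = 60,
                                    seed = 5))
  mets <- c("suv_max", "total_mtv_abs", "total_tlg_abs")
  rep <- evaluate_metrics(co, mets)
  expect_equal(rep$metric, mets)
  expect_true(all(rep$auc >= rep$ci_lo & rep$auc <= rep$ci_hi))
  expect_equal(rep$youden_j, rep$sens + rep$spec - 1)
  dm <- delong_matrix(co, mets)
  expect_equal(dm, t(dm))
  expect_equal(unname(diag(dm)), rep(1, 3))
  expect_true(all(dm >= 0 & dm <= 1))
})
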