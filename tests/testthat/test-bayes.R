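kinds3 <- c(age = "continuous", edss = "continuous", group = "factor")

sim_table <- function(n1 = 42, n2 = 21, delta = 0, seed = 1, sd = 1) {
  set.seed(seed)
  n <- n1 + n2
  grp <- factor(c(rep("MS", n1), rep("NMOSD", n2)), levels = c("MS", "NMOSD"))
  tibble::tibble(
    group = grp,
    age = rnorm(n, 40, 10),
    edss = rnorm(n, 2, 1.5),
    y = rnorm(n, 0, sd) + delta * (as.integer(grp) - 1)
  )
}

test_that("model space enumerates all additive subsets with uniform prior", {
  sp <- enumerate_models(kinds3)
  expect_equal(nrow(sp), 8)
  expect_equal(sp$prior_prob, rep(0.125, 8))
  expect_equal(sum(sp$prior_prob), 1)
  expect_equal(sp$model[1], "null")
  expect_equal(lengths(sp$terms)[1], 0L, ignore_attr = TRUE)

  sp1 <- enumerate_models(c(group = "factor"))
  expect_equal(sp1$prior_prob, c(0.5, 0.5))
  expect_error(enumerate_models(setNames(c("factor", "factor"), c("a", "a"))),
               "unique")
})

test_that("design matrix follows centering and coding conventions", {
  tab <- sim_table()
  dm0 <- design_matrix(tab, "y", character(0), kinds3)
  expect_equal(dm0$k, 0L)
  expect_equal(mean(dm0$y), 0, tolerance = 1e-12)

  dmg <- design_matrix(tab, "y", "group", kinds3)
  expect_equal(sum(dmg$X[, 1]), 0, tolerance = 1e-12)
  # balanced groups: the raw +/-1/2 coding is already centered
  bal <- sim_table(n1 = 20, n2 = 20)
  expect_equal(sort(unique(design_matrix(bal, "y", "group", kinds3)$X[, 1])),
               c(-0.5, 0.5))

  dmc <- design_matrix(tab, "y", "age", kinds3)
  expect_equal(mean(dmc$X[, 1]), 0, tolerance = 1e-12)
  expect_equal(sd(dmc$X[, 1]), 1, tolerance = 1e-12)
  tab$const <- 1
  expect_error(design_matrix(tab, "y", "const",
                             c(kinds3, const = "continuous")), "zero variance")
})

test_that("JZS Bayes factors match a dense-trapezoid quadrature oracle", {
  tab <- sim_table(seed = 3)
  tab$y <- tab$y + 0.08 * tab$age - 0.2 * tab$edss
  sp <- enumerate_models(kinds3)
  r_scales <- c(factor = 0.5, continuous = sqrt(2) / 4)
  for (i in seq_len(nrow(sp))) {
    terms <- sp$terms[[i]]
    got <- model_bf10(tab, "y", terms, kinds3, r_scales = r_scales)
    if (length(terms) == 0) {
      expect_identical(got$bf10, 1)
      next
    }
    dm <- design_matrix(tab, "y", terms, kinds3)
    want <- oracle_bf10_trapezoid(tab$y, dm$X, mean(r_scales[kinds3[terms]]^2))
    expect_equal(got$bf10, want, tolerance = 1e-6)
  }
})

test_that("group-only model equals the JZS two-sample Bayes factor", {
  tab <- sim_table(delta = 0.6, seed = 5)
  n1 <- sum(tab$group == "MS"); n2 <- sum(tab$group == "NMOSD")
  got <- model_bf10(tab, "y", "group", kinds3)$bf10
  tstat <- unname(t.test(y ~ group, data = tab, var.equal = TRUE)$statistic)
  # under the unit-information prior the factor's effective Cauchy scale on
  # the standardized mean difference is r * sqrt(n / N), N = n1 n2 / n
  n <- n1 + n2; N <- n1 * n2 / n
  want <- oracle_bf10_ttest(tstat, n1, n2, 0.5 * sqrt(n / N))
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("unrelated predictors usually earn Bayes factors below 1", {
  wins <- vapply(1:200, function(s) {
    tab <- sim_table(seed = 1000 + s)
    all(vapply(c("age", "edss", "group"), function(p) {
      model_bf10(tab, "y", p, kinds3)$bf10 < 1
    }, logical(1)))
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("posterior model probabilities and BF_M follow their identities", {
  sp <- enumerate_models(kinds3)
  expect_equal(posterior_model_probs(sp, rep(0, 8)), sp$prior_prob)
  sp2 <- enumerate_models(c(group = "factor"))
  expect_equal(posterior_model_probs(sp2, log(c(1, 3))), c(0.25, 0.75))
  set.seed(9)
  lbf <- c(0, rnorm(7, 0, 5))
  post <- posterior_model_probs(sp, lbf)
  expect_equal(sum(post), 1, tolerance = 1e-10)
  expect_error(posterior_model_probs(sp, c(0, rep(Inf, 7))), "finite")

  expect_equal(bf_m(0.3, 0.3), 1)
  expect_equal(bf_m(0.125, 0.46), (0.46 / 0.54) / (0.125 / 0.875),
               tolerance = 1e-12)
  expect_equal(bf_m(0.125, 0.46), 5.962963, tolerance = 1e-6)
  expect_true(bf_m(0.125, 0.6) > bf_m(0.125, 0.46))
  expect_error(bf_m(0.125, 1), "degenerate")
})

test_that("inclusion Bayes factors reduce and behave under nulls", {
  sp2 <- enumerate_models(c(group = "factor"))
  tab <- sim_table(delta = 0.8, seed = 2)
  bf <- model_bf10(tab, "y", "group", c(group = "factor"))$bf10
  post <- posterior_model_probs(sp2, log(c(1, bf)))
  for (v in c("all", "matched")) {
    expect_equal(inclusion_bf(sp2, post, "group", variant = v), bf,
                 tolerance = 1e-12)
  }
  sp <- enumerate_models(kinds3)
  expect_equal(inclusion_bf(sp, sp$prior_prob, "age"), 1, tolerance = 1e-12)
  expect_error(inclusion_bf(sp, sp$prior_prob, "sex"), "not in")
})

test_that("the full ANCOVA is exchangeable and detects real effects", {
  tab <- sim_table(delta = 0, seed = 7)
  tab$fw <- tab$y
  r1 <- run_bayes_ancova(tab, "fw")
  perm <- tab[sample(nrow(tab)), ]
  r2 <- run_bayes_ancova(perm, "fw")
  expect_equal(r1$models$bf10, r2$models$bf10, tolerance = 1e-12)
  expect_equal(r1$inclusion$inclusion_bf, r2$inclusion$inclusion_bf,
               tolerance = 1e-12)
  expect_equal(sum(r1$models$posterior_prob), 1, tolerance = 1e-10)
  # BF_M identity
  expect_equal(r1$models$bf_m,
               (r1$models$posterior_prob / (1 - r1$models$posterior_prob)) /
                 (r1$models$prior_prob / (1 - r1$models$prior_prob)),
               tolerance = 1e-10)

  # a 3-residual-sd group effect is detected nearly always
  hits <- vapply(1:20, function(s) {
    tb <- sim_table(delta = 3, seed = 3000 + s)
    tb$fw <- tb$y
    r <- run_bayes_ancova(tb, "fw")
    r$inclusion$inclusion_bf[r$inclusion$predictor == "group" &
                               r$inclusion$variant == "all"] > 3
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # rows with missing values are dropped with a count
  tab$fw[3] <- NA
  rd <- run_bayes_ancova(tab, "fw")
  expect_equal(rd$n_dropped, 1)
  expect_equal(rd$n, nrow(tab) - 1)
})

test_that("consistency: inclusion evidence grows with the effect", {
  meds <- vapply(c(0, 1, 2.5), function(delta) {
    bf <- vapply(1:15, function(s) {
      tb <- sim_table(delta = delta, seed = 500 + s)
      tb$fw <- tb$y
      r <- run_bayes_ancova(tb, "fw")
      r$inclusion$inclusion_bf[r$inclusion$predictor == "group" &
                                 r$inclusion$variant == "all"]
    }, numeric(1))
    median(bf)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})
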