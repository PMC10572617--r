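two_group_fixture <- function(n_per = 3, means = c(1, 3), n_feat = 1,
                              noise = 0) {
  set.seed(77)
  m <- matrix(rep(rep(means, each = n_per), n_feat), n_feat,
              2 * n_per, byrow = TRUE)
  m <- m + matrix(rnorm(length(m), 0, noise), nrow(m))
  dimnames(m) <- list(sprintf("f%03d", seq_len(n_feat)),
                      sprintf("s%d", seq_len(2 * n_per)))
  list(mat = m, condition = rep(c("case", "ctrl"), each = n_per))
}

test_that("contrast coefficient is the difference of group means", {
  fx <- two_group_fixture(means = c(3, 1))
  ds <- design_spec(fx$condition, contrast = c("case", "ctrl"))
  fit <- fit_linear_model(fx$mat, ds)
  expect_equal(unname(fit$coef), 2, tolerance = 1e-12)
  # constant feature: coefficient 0, zero residual variance
  cf <- matrix(5, 1, 6, dimnames = list("f1", sprintf("s%d", 1:6)))
  fitc <- fit_linear_model(cf, ds)
  expect_equal(unname(fitc$coef), 0)
  expect_equal(unname(fitc$s2), 0)
})

test_that("a batch aliased with condition raises a rank error", {
  fx <- two_group_fixture()
  expect_error(design_spec(fx$condition, batch = fx$condition,
                           contrast = c("case", "ctrl")) |>
                 fit_linear_model(mat = fx$mat),
               "rank deficient")
})

test_that("batch effects orthogonal to condition leave the contrast unbiased", {
  set.seed(88)
  n <- 12
  cond <- rep(c("case", "ctrl"), each = n / 2)
  batch <- rep(c("b1", "b2"), times = n / 2)
  shift <- ifelse(batch == "b2", 10, 0)
  m <- matrix(rnorm(20 * n, sd = 0.1), 20, n,
              dimnames = list(sprintf("f%02d", 1:20),
                              sprintf("s%02d", 1:n)))
  m <- m + rep(shift, each = 20) + 2 * rep(cond == "case", each = 20)
  fit <- fit_linear_model(m, design_spec(cond, batch,
                                         c("case", "ctrl")))
  expect_equal(unname(fit$coef), rep(2, 20), tolerance = 0.2)
})

test_that("moderation limits: d0 = 0 gives the classical t, d0 = Inf the pooled t", {
  set.seed(99)
  m <- matrix(rnorm(50 * 8), 50, 8,
              dimnames = list(sprintf("f%02d", 1:50),
                              sprintf("s%d", 1:8)))
  cond <- rep(c("case", "ctrl"), each = 4)
  fit <- fit_linear_model(m, design_spec(cond, contrast = c("case",
                                                            "ctrl")))
  eb0 <- ebayes_moderate(fit, d0 = 0)
  # classical two-sample t with pooled variance, equal n
  classic <- apply(m, 1, function(x)
    t.test(x[1:4], x[5:8], var.equal = TRUE)$statistic)
  expect_equal(unname(eb0$t_mod), unname(classic), tolerance = 1e-10)
  expect_equal(unname(eb0$s2_post), unname(fit$s2), tolerance = 1e-12)

  ebI <- ebayes_moderate(fit, d0 = Inf)
  expect_equal(unname(ebI$s2_post), rep(ebI$s0_2, 50))
})

test_that("moderated statistics match the reference empirical-Bayes pipeline", {
  skip_if_not_installed("limma")
  set.seed(111)
  m <- matrix(rnorm(200 * 10, sd = rep(sqrt(rchisq(200, 4) / 4), 10)),
              200, 10,
              dimnames = list(sprintf("f%03d", 1:200),
                              sprintf("s%02d", 1:10)))
  cond <- rep(c("case", "ctrl"), each = 5)
  fit <- fit_linear_model(m, design_spec(cond, contrast = c("case",
                                                            "ctrl")))
  eb <- ebayes_moderate(fit)
  design <- model.matrix(~ 0 + factor(cond, levels = c("case", "ctrl")))
  colnames(design) <- c("case", "ctrl")
  lfit <- limma::lmFit(m, design)
  lfit <- limma::contrasts.fit(lfit,
                               limma::makeContrasts(case - ctrl,
                                                    levels = design))
  lfit <- limma::eBayes(lfit)
  expect_equal(unname(eb$d0), unname(lfit$df.prior), tolerance = 1e-6)
  expect_equal(unname(eb$s0_2), unname(lfit$s2.prior), tolerance = 1e-6)
  expect_equal(unname(eb$t_mod), unname(lfit$t[, 1]), tolerance = 1e-8)
  expect_equal(unname(eb$p), unname(lfit$p.value[, 1]), tolerance = 1e-8)
})

test_that("BH adjustment matches hand evaluation and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_by_hand(p))
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in p
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])      # order-invariant
  }
})

test_that("differential table recovers planted circuit shifts", {
  set.seed(222)
  n_feat <- 500; n_per <- 30
  planted <- sprintf("f%03d", 1:20)
  m <- matrix(rnorm(n_feat * 2 * n_per), n_feat, 2 * n_per,
              dimnames = list(sprintf("f%03d", 1:n_feat),
                              sprintf("s%02d", 1:(2 * n_per))))
  cond <- rep(c("tumor", "normal"), each = n_per)
  m[planted, cond == "tumor"] <- m[planted, cond == "tumor"] + 1.5
  res <- differential_table(m, cond, contrasts = list(c("tumor",
                                                        "normal")))
  sig <- res$significant[[1]]
  expect_gte(sum(planted %in% sig), 16)
  fdp <- sum(!(sig %in% planted)) / max(length(sig), 1)
  expect_lte(fdp, 0.15)
  tab <- res$tables[[1]]
  expect_true(all(tab$fdr >= tab$p - 1e-15))
  expect_equal(tab$direction, ifelse(tab$log2FC >= 0, "up", "down"))
})

test_that("cross-contrast intersection averages shared significant features", {
  set.seed(333)
  n_per <- 20
  m <- matrix(rnorm(100 * 3 * n_per, sd = 0.3), 100, 3 * n_per,
              dimnames = list(sprintf("f%03d", 1:100),
                              sprintf("s%02d", 1:(3 * n_per))))
  cond <- rep(c("tumor", "adipose", "muscle"), each = n_per)
  # f001 up against both control tissues; f002 up in one, down in the other
  m["f001", cond == "tumor"] <- m["f001", cond == "tumor"] + 2
  m["f002", cond == "adipose"] <- m["f002", cond == "adipose"] - 2
  m["f002", cond == "muscle"] <- m["f002", cond == "muscle"] + 2
  res <- differential_table(m, cond,
                            contrasts = list(c("tumor", "adipose"),
                                             c("tumor", "muscle")))
  inter <- res$intersection
  expect_true("f001" %in% inter$feature_id)
  expect_false("f002" %in% inter$feature_id)  # opposite directions
  i <- match("f001", inter$feature_id)
  lfc1 <- res$tables[[1]]$log2FC[match("f001",
                                       res$tables[[1]]$feature_id)]
  lfc2 <- res$tables[[2]]$log2FC[match("f001",
                                       res$tables[[2]]$feature_id)]
  expect_equal(inter$log2FC[i], mean(c(lfc1, lfc2)))
  expect_equal(inter$n[i], 2)
})
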