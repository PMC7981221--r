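# fits here are deliberately small; the heavier recovery studies live in
# test-acceptance.R

make_glm_table <- function(n = 3000, n_tag = 30, n_recv = 10,
                           sigma_tag = 0, sigma_recv = 0, seed = 5,
                           beta_night = 0.5) {
  sim <- simulate_model_table(
    n_per_species = c(gray_reef = ceiling(n_tag / 2),
                      silvertip = floor(n_tag / 2)),
    movements_per_ind = ceiling(n / n_tag), n_receivers = n_recv,
    beta = list(beta0 = -0.4,
                beta_species = c(gray_reef = 0, silvertip = 0.3),
                beta_night = beta_night, beta_wet = 0.2),
    sigma_tag = sigma_tag, sigma_receiver = sigma_recv, seed = seed)
  sim$table
}

test_that("VIF is 1 for orthogonal predictors and 1/(1-r^2) for a pair", {
  n <- 400
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, 1), each = n / 2)          # orthogonal to x1
  tab <- data.frame(x1 = x1, x2 = x2)
  v <- vif(tab, c("x1", "x2"))
  expect_equal(v$vif, c(1, 1), tolerance = 1e-10)
  expect_true(attr(v, "gate_ok"))

  set.seed(9)
  z1 <- rnorm(n)
  e <- residuals(lm(rnorm(n) ~ z1))          # exactly orthogonal noise
  z2 <- 0.9 * scale(z1)[, 1] + sqrt(1 - 0.81) * scale(e)[, 1]
  tab2 <- data.frame(z1 = z1, z2 = z2)
  r <- cor(z1, z2)
  v2 <- vif(tab2, c("z1", "z2"))
  expect_equal(v2$vif, rep(1 / (1 - r^2), 2), tolerance = 1e-8)
})

test_that("perfect collinearity yields infinite VIF and a failed gate", {
  x <- rnorm(100)
  tab <- data.frame(a = x, b = 2 * x, c = rnorm(100))
  v <- suppressWarnings(vif(tab, c("a", "b", "c")))
  expect_true(any(!is.finite(v$vif) | v$vif > 1e6))
  expect_false(attr(v, "gate_ok"))
})

test_that("AICc reproduces its closed form from logLik, k, n", {
  expect_equal(aicc_from(-100, 5, 50), 200 + 10 + 2 * 5 * 6 / 44)
  tab <- make_glm_table(n = 600, seed = 3)
  fit <- fit_glmm(tab, c("species", "diel"))
  ll <- logLik(fit)
  expect_equal(aicc(fit),
               -2 * as.numeric(ll) + 2 * attr(ll, "df") +
                 2 * attr(ll, "df") * (attr(ll, "df") + 1) /
                   (nobs(fit) - attr(ll, "df") - 1))
})

test_that("with zero random-effect variance the GLMM reduces to the GLM", {
  tab <- make_glm_table(n = 4000, sigma_tag = 0, sigma_recv = 0, seed = 11)
  fit <- fit_glmm(tab, c("species", "diel", "season"))
  expect_true(model_converged(fit))
  vc <- variance_components(fit)
  expect_lt(max(vc$variance), 1e-3)
  glm_fit <- glm(label ~ species + diel + season, binomial(), data = tab)
  expect_equal(unname(glmmTMB::fixef(fit)$cond), unname(coef(glm_fit)),
               tolerance = 1e-3)
})

test_that("the global fit recovers a known night effect within 2 SE", {
  sim <- simulate_model_table(
    n_per_species = c(gray_reef = 40, silvertip = 40),
    movements_per_ind = 30, n_receivers = 15,
    beta = list(beta0 = -0.475,
                beta_species = c(gray_reef = 0, silvertip = 0.449),
                beta_night = 0.5, beta_wet = 0.159),
    sigma_tag = 0.5, sigma_receiver = 0.5, seed = 2)
  fit <- fit_glmm(sim$table, c("species", "diel", "season"))
  ct <- coef_table(fit)
  night <- ct[term == "dielnight"]
  expect_lt(abs(night$estimate - 0.5), 2 * night$std_error)
  expect_equal(night$ci_lower, night$estimate - qnorm(0.975) * night$std_error)
})

test_that("submodel enumeration respects marginality and matches brute force", {
  global <- c("species", "sex", "log_size", "diel", "season",
              "species:sex", "species:log_size", "species:diel",
              "species:season")
  subs <- enumerate_submodels(global)
  # independent oracle: filter all 2^9 term subsets for marginality
  all_sets <- unlist(lapply(0:511, function(mask) {
    s <- global[bitwAnd(mask, 2^(0:8)) > 0]
    ints <- grep(":", s, value = TRUE)
    ok <- all(vapply(strsplit(ints, ":"),
                     function(p) all(p %in% s), TRUE))
    if (ok) paste(sort(s), collapse = "+") else NA_character_
  }))
  all_sets <- unique(all_sets[!is.na(all_sets)])
  got <- vapply(subs, function(s) paste(sort(s), collapse = "+"), "")
  expect_setequal(got, all_sets)
  expect_equal(length(subs), 97L)
  expect_true(any(got == ""))  # intercept-only always present
  expect_error(enumerate_submodels(c("species:diel", "species")),
               "without both main effects")
})

test_that("dredge ranks by AICc with weights summing to one", {
  tab <- make_glm_table(n = 1200, n_tag = 20, sigma_tag = 0.4,
                        sigma_recv = 0.4, seed = 8)
  ms <- suppressWarnings(dredge_models(tab, c("species", "diel")))
  expect_equal(nrow(ms$table), 4L)
  expect_equal(sum(ms$table$weight), 1, tolerance = 1e-9)
  expect_true(!is.unsorted(ms$table$AICc))
  expect_true("" %in% ms$table$terms)
  expect_equal(ms$table$delta[1], 0)
})

test_that("nested-model removal drops supersets of better models only", {
  fake <- function(aicc_a, aicc_b) {
    tab <- data.table::data.table(
      model_id = 1:2, terms = c("diel", "diel + species"),
      n_terms = 1:2, k = 3:4, logLik = c(-10, -10),
      AICc = c(aicc_a, aicc_b), converged = TRUE)
    data.table::setorder(tab, AICc)
    tab[, delta := AICc - AICc[1]]
    tab[, weight := exp(-delta / 2) / sum(exp(-delta / 2))]
    structure(list(table = tab, fits = list(NULL, NULL)),
              class = "telegaps_modelset")
  }
  pruned <- remove_nested(fake(100, 102))   # simpler model better
  expect_equal(pruned$table$terms, "diel")
  kept <- remove_nested(fake(102, 100))     # complex model better: keep both
  expect_equal(nrow(kept$table), 2L)
  expect_equal(sum(kept$table$weight), 1, tolerance = 1e-9)
})

test_that("selection reports single survivor, dominant model, or averages", {
  tab <- make_glm_table(n = 1000, n_tag = 20, sigma_tag = 0.4,
                        sigma_recv = 0.4, seed = 12)
  f1 <- fit_glmm(tab, "diel")
  f2 <- fit_glmm(tab, c("diel", "species"))
  mk <- function(w1) {
    t2 <- data.table::data.table(
      model_id = 1:2, terms = c("diel", "diel + species"),
      n_terms = 1:2, k = 3:4, logLik = c(-1, -1),
      AICc = c(0, -2 * log(1 / w1 - 1)), converged = TRUE)
    data.table::setorder(t2, AICc)
    t2[, delta := AICc - AICc[1]]
    t2[, weight := exp(-delta / 2) / sum(exp(-delta / 2))]
    structure(list(table = t2, fits = list(f1, f2)),
              class = "telegaps_modelset")
  }
  single <- structure(list(table = mk(0.95)$table[1], fits = list(f1, f2)),
                      class = "telegaps_modelset")
  expect_equal(select_or_average(single)$type, "single")

  dominant <- mk(0.95)
  expect_equal(select_or_average(dominant)$type, "best")

  split <- mk(0.6)
  sel <- select_or_average(split)
  expect_equal(sel$type, "averaged")
  # zero-substitution averaging by hand for the species coefficient
  w <- split$table$weight
  ids <- split$table$model_id
  cts <- lapply(ids, function(i) coef_table(split$fits[[i]]))
  b <- vapply(cts, function(ct) {
    i <- match("speciessilvertip", ct$term); if (is.na(i)) 0 else ct$estimate[i]
  }, 0)
  se <- vapply(cts, function(ct) {
    i <- match("speciessilvertip", ct$term); if (is.na(i)) 0 else ct$std_error[i]
  }, 0)
  est <- sum(w * b)
  se_u <- sqrt(sum(w * (se^2 + (b - est)^2)))
  row <- sel$coefficients[term == "speciessilvertip"]
  expect_equal(row$estimate, est)
  expect_equal(row$std_error, se_u)
})

test_that("Nakagawa R2 follows the logit-scale variance decomposition", {
  r2 <- nakagawa_r2_from(1, 2)
  expect_equal(unname(r2["R2m"]), 1 / (3 + pi^2 / 3), tolerance = 1e-9)
  expect_equal(unname(r2["R2c"]), 3 / (3 + pi^2 / 3), tolerance = 1e-9)
  expect_equal(unname(nakagawa_r2_from(0, 2)["R2m"]), 0)

  tab <- make_glm_table(n = 1500, n_tag = 25, sigma_tag = 0.5,
                        sigma_recv = 0.5, seed = 4)
  fit <- fit_glmm(tab, c("species", "diel"))
  r2f <- nakagawa_r2(fit)
  # independent reconstruction from the design matrix and fixed effects
  X <- model.matrix(~ species + diel, data = tab)
  eta <- as.numeric(X %*% glmmTMB::fixef(fit)$cond)
  vre <- sum(variance_components(fit)$variance)
  expect_equal(unname(r2f), unname(nakagawa_r2_from(var(eta), vre)),
               tolerance = 1e-8)
  expect_gte(r2f[["R2c"]], r2f[["R2m"]])
})

test_that("conditional modes recover and shrink individual intercepts", {
  sim <- simulate_model_table(
    n_per_species = c(gray_reef = 40, silvertip = 40),
    movements_per_ind = 40, n_receivers = 10,
    beta = list(beta0 = 0, beta_species = c(gray_reef = 0, silvertip = 0),
                beta_night = 0, beta_wet = 0),
    sigma_tag = 1, sigma_receiver = 0.1, seed = 31)
  fit <- fit_glmm(sim$table, character())
  cm <- conditional_modes(fit, individuals = data.table::data.table(
    tag_id = names(sim$params$u_tag),
    species = rep(c("gray_reef", "silvertip"), each = 40)))
  tags <- cm$modes[grpvar == "tag_id"]
  expect_equal(nrow(tags), 80L)
  rho <- cor(tags$mode, sim$params$u_tag[tags$level], method = "spearman")
  expect_gt(rho, 0.8)
  expect_true(all(c("n", "fraction_significant") %in%
                    names(cm$species_significant)))
  # shrinkage: modes no larger than raw per-level logit offsets
  raw <- sim$table[, .(p = (sum(label) + 0.5) / (.N + 1)), by = tag_id]
  raw[, offset := qlogis(p) - glmmTMB::fixef(fit)$cond[["(Intercept)"]]]
  merged <- merge(tags, raw, by.x = "level", by.y = "tag_id")
  expect_gte(mean(abs(merged$mode) <= abs(merged$offset) + 1e-8), 0.95)
})

test_that("cross-validated AUC is 1 on separable data and errors without both classes", {
  set.seed(77)
  n <- 400
  tab <- data.table::data.table(
    label = rep(0:1, each = n / 2),
    species = sample(c("gray_reef", "silvertip"), n, TRUE),
    sex = "F", log_size = log(120),
    diel = rep(c("day", "night"), each = n / 2),
    season = sample(c("dry", "wet"), n, TRUE),
    tag_id = sprintf("T%02d", sample(20, n, TRUE)),
    receiver_id = sprintf("R%02d", sample(8, n, TRUE)))
  auc <- suppressWarnings(crossval_auc(tab, "diel", seed = 1))
  expect_equal(as.numeric(auc), 1.0)

  one_class <- data.table::copy(tab)[, label := 1L]
  expect_error(suppressWarnings(crossval_auc(one_class, "diel", seed = 1)),
               "both classes")
})

test_that("held-out AUC hovers at chance when labels are shuffled", {
  tab <- make_glm_table(n = 1200, n_tag = 24, sigma_tag = 0.3,
                        sigma_recv = 0.3, seed = 15)
  set.seed(99)
  tab[, label := sample(label)]
  aucs <- vapply(1:3, function(s)
    as.numeric(suppressWarnings(crossval_auc(tab, c("species", "diel"),
                                             seed = s))), 0)
  expect_true(all(aucs > 0.35 & aucs < 0.65))
})

test_that("residual diagnostics are deterministic and flag serial structure", {
  tab <- make_glm_table(n = 1000, n_tag = 20, seed = 16)
  fit <- fit_glmm(tab, "diel")
  d1 <- residual_diagnostics(fit)
  d2 <- residual_diagnostics(fit)
  expect_identical(d1, d2)
  expect_equal(nrow(d1$acf), 20L)
  expect_gt(d1$spread_ratio, 0)

  # blocky labels induce strong lag-1 autocorrelation in data order
  blocky <- data.table::copy(tab)[, label := rep(rep(0:1, each = 50),
                                                 length.out = .N)]
  fitb <- suppressWarnings(fit_glmm(blocky, character()))
  db <- residual_diagnostics(fitb)
  expect_gt(db$acf$acf[1], 0.5)
  expect_true(db$acf$flagged[1])
})

test_that("the mixed-model fit agrees with an independent engine", {
  skip_if_not_installed("lme4")
  tab <- make_glm_table(n = 1500, n_tag = 25, sigma_tag = 0.5,
                        sigma_recv = 0.5, seed = 27)
  fit <- fit_glmm(tab, c("species", "diel"))
  ref <- lme4::glmer(label ~ species + diel + (1 | tag_id) + (1 | receiver_id),
                     data = tab, family = binomial)
  expect_equal(unname(glmmTMB::fixef(fit)$cond),
               unname(lme4::fixef(ref)), tolerance = 5e-3)
  vc_ref <- as.data.frame(lme4::VarCorr(ref))
  vc <- variance_components(fit)
  expect_equal(vc$variance[match(vc_ref$grp, vc$group)], vc_ref$vcov,
               tolerance = 0.05)
})
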