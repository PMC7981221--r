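#' Variance inflation factors for the fixed-effect predictors
#'
#' Computes `VIF_j = 1 / (1 - R2_j)`, where `R2_j` is from regressing the
#' j-th model-matrix column (categorical predictors as indicator contrasts)
#' on all the others. Predictors with VIF above `threshold` (default 5)
#' fail the collinearity gate and should not enter the global model
#' together.
#'
#' @param table Modelling table from [build_model_table()].
#' @param predictors Character vector of predictor columns (>= 2).
#' @param threshold Gate value (default 5).
#' @return `data.table` with `predictor`, `vif`; attribute `gate_ok` is
#'   `TRUE` when every VIF is at or below `threshold`. Perfectly collinear
#'   predictors get `Inf`.
#' @export
vif <- function(table, predictors, threshold = 5) {
  if (length(predictors) < 2L) stop("need at least two predictors")
  df <- as.data.frame(table)[, predictors, drop = FALSE]
  df[] <- lapply(df, function(x) if (is.character(x)) factor(x) else x)
  constant <- vapply(df, function(x) length(unique(x)) < 2L, TRUE)
  if (any(constant)) {
    message("constant predictor(s) excluded from VIF: ",
            paste(names(df)[constant], collapse = ", "))
    df <- df[, !constant, drop = FALSE]
  }
  if (ncol(df) < 2L) stop("fewer than two varying predictors")
  X <- model.matrix(~ ., data = df)[, -1L, drop = FALSE]
  keep <- apply(X, 2L, function(col) sd(col) > 0)
  X <- X[, keep, drop = FALSE]
  R <- cor(X)
  v <- tryCatch(diag(solve(R)), error = function(e) NULL)
  if (is.null(v)) {
    # singular: per-column R^2, aliased columns reported as Inf
    v <- vapply(seq_len(ncol(X)), function(j) {
      r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, 0)
    names(v) <- colnames(X)
  }
  out <- data.table(predictor = names(v), vif = as.numeric(v))
  setattr(out, "gate_ok", all(out$vif <= threshold))
  out[]
}

#' Fit a binomial mixed model for out-of-range movement
#'
#' Maximum-likelihood (Laplace) fit of
#' `logit P(out_of_range) = X beta + u_tag + u_receiver`, with independent
#' zero-mean normal random intercepts for individual and receiver, via
#' `glmmTMB` with `family = binomial(link = "logit")`.
#'
#' @param table Modelling table from [build_model_table()].
#' @param fixed Character vector of fixed-effect terms, e.g.
#'   `c("species", "diel", "species:diel")`; empty for intercept-only.
#' @param re Grouping factors given random intercepts (crossed).
#' @return The `glmmTMB` fit. Use [model_converged()] to check status.
#' @export
fit_glmm <- function(table, fixed = character(),
                     re = c("tag_id", "receiver_id")) {
  df <- as.data.frame(table)
  for (col in c("species", "sex", "diel", "season", re))
    if (col %in% names(df)) df[[col]] <- factor(df[[col]])
  rhs <- paste(c(if (length(fixed) > 0L) fixed else "1",
                 sprintf("(1 | %s)", re)), collapse = " + ")
  f <- as.formula(paste("label ~", rhs))
  glmmTMB::glmmTMB(f, data = df, family = stats::binomial(link = "logit"))
}

#' Did a mixed-model fit converge?
#'
#' @param fit A `glmmTMB` fit.
#' @return `TRUE` when the optimiser reported success and the Hessian is
#'   positive definite.
#' @export
model_converged <- function(fit) {
  isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`, with `k` the number of
#' estimated parameters (fixed effects plus variance components) and `n` the
#' number of movement rows.
#'
#' @param loglik Log-likelihood.
#' @param k Parameter count.
#' @param n Observation count.
#' @return AICc value.
#' @export
aicc_from <- function(loglik, k, n) {
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @rdname aicc_from
#' @param fit A fitted model with `logLik()` and `nobs()` methods.
#' @export
aicc <- function(fit) {
  ll <- logLik(fit)
  aicc_from(as.numeric(ll), attr(ll, "df"), nobs(fit))
}

#' Table-style coefficient summary
#'
#' Wald summary of the fixed effects: estimate, standard error, lower and
#' upper bounds at the 97.5% normal quantile (estimate +/- 1.96 SE), z and
#' two-sided p value.
#'
#' @param fit A `glmmTMB` fit.
#' @return `data.table` with columns `term`, `estimate`, `std_error`,
#'   `ci_lower`, `ci_upper`, `z`, `p`.
#' @export
coef_table <- function(fit) {
  sm <- summary(fit)$coefficients$cond
  z975 <- qnorm(0.975)
  data.table(term = rownames(sm),
             estimate = sm[, "Estimate"],
             std_error = sm[, "Std. Error"],
             ci_lower = sm[, "Estimate"] - z975 * sm[, "Std. Error"],
             ci_upper = sm[, "Estimate"] + z975 * sm[, "Std. Error"],
             z = sm[, "z value"],
             p = sm[, "Pr(>|z|)"])
}

#' Enumerate marginality-respecting submodels of a global term set
#'
#' Every subset of the main effects, combined with every subset of the
#' interaction terms whose two parent main effects are both present. The
#' intercept-only model is always included.
#'
#' @param global_fixed Character vector of terms; interactions written
#'   `"a:b"`.
#' @return List of character vectors (term sets), including `character(0)`.
#' @export
enumerate_submodels <- function(global_fixed) {
  ints <- grep(":", global_fixed, fixed = TRUE, value = TRUE)
  mains <- setdiff(global_fixed, ints)
  parents <- strsplit(ints, ":", fixed = TRUE)
  bad <- vapply(parents, function(p) !all(p %in% mains), TRUE)
  if (any(bad))
    stop("interaction(s) without both main effects in the global model: ",
         paste(ints[bad], collapse = ", "))
  out <- list()
  for (mmask in seq_len(2^length(mains)) - 1L) {
    msub <- mains[bitwAnd(mmask, 2^(seq_along(mains) - 1L)) > 0L]
    ok_ints <- ints[vapply(parents, function(p) all(p %in% msub), TRUE)]
    for (imask in seq_len(2^length(ok_ints)) - 1L) {
      isub <- ok_ints[bitwAnd(imask, 2^(seq_along(ok_ints) - 1L)) > 0L]
      out[[length(out) + 1L]] <- c(msub, isub)
    }
  }
  out
}

#' All-subsets model set ranked by AICc
#'
#' Fits every marginality-respecting submodel of the global fixed-effect set
#' (random intercepts always retained), ranks by AICc, and attaches delta
#' AICc and Akaike weights. Non-converged candidates are excluded from the
#' ranking with a warning.
#'
#' @param table Modelling table.
#' @param global_fixed Global fixed-effect term set.
#' @param re Random-intercept factors.
#' @param progress Emit a message per fitted candidate.
#' @return A `telegaps_modelset`: list with `table` (ranking) and `fits`.
#' @export
dredge_models <- function(table, global_fixed,
                          re = c("tag_id", "receiver_id"),
                          progress = FALSE) {
  subsets <- enumerate_submodels(global_fixed)
  fits <- vector("list", length(subsets))
  rows <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    terms_i <- subsets[[i]]
    if (progress) message("fitting [", i, "/", length(subsets), "] ",
                          paste(terms_i, collapse = " + "))
    fit <- tryCatch(fit_glmm(table, terms_i, re), error = function(e) NULL)
    ok <- !is.null(fit) && model_converged(fit)
    fits[[i]] <- fit
    ll <- if (!is.null(fit)) logLik(fit) else NA
    rows[[i]] <- data.table(
      model_id = i,
      terms = paste(sort(terms_i), collapse = " + "),
      n_terms = length(terms_i),
      k = if (!is.null(fit)) attr(ll, "df") else NA_integer_,
      logLik = if (!is.null(fit)) as.numeric(ll) else NA_real_,
      AICc = if (ok) aicc(fit) else NA_real_,
      converged = ok)
  }
  tab <- rbindlist(rows)
  if (any(!tab$converged))
    warning(sum(!tab$converged), " candidate model(s) failed to converge ",
            "and were excluded from ranking")
  ms <- list(table = tab[converged == TRUE], fits = fits)
  class(ms) <- "telegaps_modelset"
  rank_modelset(ms)
}

#' @noRd
rank_modelset <- function(ms) {
  setorder(ms$table, AICc)
  ms$table[, delta := AICc - AICc[1L]]
  ms$table[, weight := exp(-delta / 2) / sum(exp(-delta / 2))]
  ms
}

#' @export
print.telegaps_modelset <- function(x, ...) {
  cat("Model set:", nrow(x$table), "candidate(s)\n")
  print(x$table[, .(terms, k, logLik, AICc, delta, weight)], digits = 4)
  invisible(x)
}

#' Remove models nested in better-supported ones
#'
#' Drops every candidate whose fixed-effect term set is a strict superset of
#' a model with lower (better) AICc — more complex versions of simpler,
#' better models add selection noise without support. Weights are
#' renormalised over the survivors.
#'
#' @param ms A `telegaps_modelset` from [dredge_models()].
#' @return Pruned `telegaps_modelset`.
#' @export
remove_nested <- function(ms) {
  tab <- ms$table
  term_sets <- strsplit(tab$terms, " + ", fixed = TRUE)
  term_sets[tab$terms == ""] <- list(character(0))
  n <- nrow(tab)
  drop <- logical(n)
  for (i in seq_len(n)) {        # tab sorted by AICc: j < i => AICc_j <= AICc_i
    for (j in seq_len(i - 1L)) {
      if (tab$AICc[j] < tab$AICc[i] &&
          length(term_sets[[j]]) < length(term_sets[[i]]) &&
          all(term_sets[[j]] %in% term_sets[[i]])) {
        drop[i] <- TRUE
        break
      }
    }
  }
  ms$table <- tab[!drop]
  rank_modelset(ms)
}

#' Final inference from a pruned model set
#'
#' If a single model survives nested-model removal it is reported directly.
#' Otherwise, if the best model's Akaike weight is at least
#' `weight_threshold` (default 0.9) the best model is reported; below that,
#' coefficients are model-averaged across the surviving set — by default
#' *full* (zero-substitution) averaging, where a model not containing a term
#' contributes an estimate of 0, with unconditional standard errors
#' `sqrt(sum_i w_i (se_i^2 + (b_i - b_avg)^2))`. `averaging = "natural"`
#' instead averages only over the models containing each term.
#'
#' @param ms A `telegaps_modelset` (after [remove_nested()]).
#' @param weight_threshold Weight above which the best model is reported
#'   alone.
#' @param averaging `"full"` or `"natural"`.
#' @return List with `type` (`"single"`, `"best"`, or `"averaged"`), `fit`
#'   (the best surviving fit — the basis for R-squared, random-effect and
#'   prediction summaries), `terms`, and `coefficients` (a [coef_table()]
#'   style table).
#' @export
select_or_average <- function(ms, weight_threshold = 0.9,
                              averaging = c("full", "natural")) {
  averaging <- match.arg(averaging)
  if (nrow(ms$table) == 0L) stop("empty model set")
  best_id <- ms$table$model_id[1L]
  best_fit <- ms$fits[[best_id]]
  best_terms <- ms$table$terms[1L]
  if (nrow(ms$table) == 1L) {
    return(list(type = "single", fit = best_fit, terms = best_terms,
                coefficients = coef_table(best_fit)))
  }
  if (ms$table$weight[1L] >= weight_threshold) {
    return(list(type = "best", fit = best_fit, terms = best_terms,
                coefficients = coef_table(best_fit)))
  }
  cts <- lapply(ms$table$model_id, function(id) coef_table(ms$fits[[id]]))
  w <- ms$table$weight
  terms_all <- unique(unlist(lapply(cts, `[[`, "term")))
  avg <- rbindlist(lapply(terms_all, function(tm) {
    b <- vapply(cts, function(ct) {
      i <- match(tm, ct$term); if (is.na(i)) 0 else ct$estimate[i]
    }, 0)
    se <- vapply(cts, function(ct) {
      i <- match(tm, ct$term); if (is.na(i)) 0 else ct$std_error[i]
    }, 0)
    present <- vapply(cts, function(ct) tm %in% ct$term, TRUE)
    if (averaging == "full") {
      est <- sum(w * b)
      se_u <- sqrt(sum(w * (se^2 + (b - est)^2)))
    } else {
      wp <- w[present] / sum(w[present])
      est <- sum(wp * b[present])
      se_u <- sqrt(sum(wp * (se[present]^2 + (b[present] - est)^2)))
    }
    z975 <- qnorm(0.975)
    zval <- if (se_u > 0) est / se_u else NA_real_
    data.table(term = tm, estimate = est, std_error = se_u,
               ci_lower = est - z975 * se_u, ci_upper = est + z975 * se_u,
               z = zval, p = 2 * pnorm(-abs(zval)))
  }))
  list(type = "averaged", fit = best_fit, terms = best_terms,
       coefficients = avg)
}

#' Nakagawa marginal and conditional R-squared
#'
#' For a binomial-logit mixed model,
#' `R2m = var_f / (var_f + sum(var_re) + pi^2/3)` and
#' `R2c = (var_f + sum(var_re)) / (var_f + sum(var_re) + pi^2/3)`, where
#' `var_f` is the variance of the fixed-effect linear predictor over the
#' data and `pi^2/3` the logistic distribution-specific residual variance.
#'
#' @param fit A converged `glmmTMB` binomial fit.
#' @return Named numeric vector `c(R2m = ..., R2c = ...)`.
#' @export
nakagawa_r2 <- function(fit) {
  eta_f <- predict(fit, re.form = NA, type = "link")
  vc <- glmmTMB::VarCorr(fit)$cond
  var_re <- sum(vapply(vc, function(m) sum(diag(m)), 0))
  nakagawa_r2_from(var(eta_f), var_re)
}

#' @rdname nakagawa_r2
#' @param var_fixed Variance of the fixed-effect linear predictor.
#' @param var_random Summed random-intercept variances.
#' @export
nakagawa_r2_from <- function(var_fixed, var_random) {
  denom <- var_fixed + var_random + pi^2 / 3
  c(R2m = var_fixed / denom, R2c = (var_fixed + var_random) / denom)
}

#' Random-effect variance components
#'
#' @param fit A `glmmTMB` fit.
#' @return `data.table` with `group`, `variance`, `sd` (logit scale).
#' @export
variance_components <- function(fit) {
  vc <- glmmTMB::VarCorr(fit)$cond
  data.table(group = names(vc),
             variance = vapply(vc, function(m) sum(diag(m)), 0),
             sd = sqrt(vapply(vc, function(m) sum(diag(m)), 0)))
}

#' Conditional modes of the random effects
#'
#' Empirical-Bayes mode and conditional SD for every grouping level, with
#' 95% intervals (`mode +/- 1.96 SD`). A level is flagged significant when
#' its interval excludes zero — an individual (or receiver) whose
#' out-of-range tendency departs from the population intercept. When tag
#' metadata are supplied, the fraction of significant individuals is
#' reported per species.
#'
#' @param fit A converged `glmmTMB` fit.
#' @param individuals Optional tag metadata for per-species fractions.
#' @return List: `modes` (`data.table` with `grpvar`, `level`, `mode`,
#'   `cond_sd`, `lo`, `hi`, `significant`) and, with metadata,
#'   `species_significant` (`data.table` of per-species fractions over
#'   `tag_id` levels).
#' @export
conditional_modes <- function(fit, individuals = NULL) {
  re <- as.data.frame(glmmTMB::ranef(fit, condVar = TRUE))
  z975 <- qnorm(0.975)
  modes <- data.table(grpvar = as.character(re$grpvar),
                      level = as.character(re$grp),
                      mode = re$condval,
                      cond_sd = re$condsd)
  modes[, lo := mode - z975 * cond_sd]
  modes[, hi := mode + z975 * cond_sd]
  modes[, significant := lo > 0 | hi < 0]
  out <- list(modes = modes[])
  if (!is.null(individuals)) {
    ind <- as.data.table(individuals)
    tags <- modes[grpvar == "tag_id"]
    tags[ind, species := i.species, on = c(level = "tag_id")]
    out$species_significant <- tags[!is.na(species),
      .(n = .N, n_significant = sum(significant),
        fraction_significant = mean(significant)), by = species]
  }
  out
}

#' Cross-validated AUC of the final model
#'
#' Splits the movements into train/test at movement level (stratified by
#' species), fits the given fixed-effect structure on the training fraction,
#' predicts held-out probabilities (grouping levels unseen in training get a
#' zero random-effect contribution, i.e. population-level prediction), and
#' scores them with the area under the ROC curve — a rank statistic, so any
#' monotone transform of the probabilities gives the same value. AUC 0.5 is
#' chance; 1 is perfect ranking.
#'
#' @param table Modelling table.
#' @param fixed Fixed-effect terms of the model to validate.
#' @param train_fraction Training proportion (default 0.8).
#' @param seed RNG seed for the split (recorded in the run log).
#' @param re Random-intercept factors.
#' @return AUC (numeric scalar); attributes `n_train`, `n_test`.
#' @export
crossval_auc <- function(table, fixed, train_fraction = 0.8, seed = 42L,
                         re = c("tag_id", "receiver_id")) {
  tab <- as.data.table(table)
  if (!is.null(seed)) set.seed(seed)
  idx <- unlist(lapply(split(seq_len(nrow(tab)), tab$species), function(i) {
    sample(i, floor(length(i) * train_fraction))
  }), use.names = FALSE)
  train <- tab[idx]
  test <- tab[-idx]
  if (length(unique(test$label)) < 2L)
    stop("held-out split lacks both classes; cannot compute AUC")
  fit <- fit_glmm(train, fixed, re)
  newdf <- as.data.frame(test)
  for (col in c("species", "sex", "diel", "season", re))
    if (col %in% names(newdf)) newdf[[col]] <- factor(newdf[[col]])
  p <- predict(fit, newdata = newdf, type = "response",
               allow.new.levels = TRUE)
  roc <- pROC::roc(response = test$label, predictor = p,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  out <- as.numeric(pROC::auc(roc))
  attr(out, "n_train") <- nrow(train)
  attr(out, "n_test") <- nrow(test)
  out
}

#' Numeric residual diagnostics
#'
#' Advisory (never gating) report on a fitted model: autocorrelation of the
#' Pearson residuals in data order at lags 1..`max_lag` against the
#' `2/sqrt(n)` white-noise band, and the spread of residuals across fitted-
#' value quartile bins as a heteroscedasticity summary.
#'
#' @param fit A `glmmTMB` fit.
#' @param max_lag Largest lag (default 20).
#' @return List: `acf` (`data.table` of `lag`, `acf`, `flagged`),
#'   `acf_band`, `spread` (per-bin residual SD), `spread_ratio`
#'   (max SD / min SD across bins).
#' @export
residual_diagnostics <- function(fit, max_lag = 20L) {
  r <- residuals(fit, type = "pearson")
  n <- length(r)
  ac <- acf(r, lag.max = max_lag, plot = FALSE)$acf[-1L]
  band <- 2 / sqrt(n)
  fv <- fitted(fit)
  breaks <- unique(quantile(fv, probs = seq(0, 1, 0.25)))
  bin <- if (length(breaks) < 3L) rep(1L, n) else
    cut(fv, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  spread <- vapply(split(r, bin), sd, 0)
  list(acf = data.table(lag = seq_len(max_lag), acf = as.numeric(ac),
                        flagged = abs(as.numeric(ac)) > band),
       acf_band = band,
       spread = spread,
       spread_ratio = max(spread) / min(spread))
}
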