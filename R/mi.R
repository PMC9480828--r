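#' Configure chained-equations multiple imputation
#'
#' @param n_chains Number of independent chains (at least 2, so that the
#'   Gelman-Rubin diagnostic is defined).
#' @param stage1_iters Burn-in sweeps of the first stage.
#' @param stage2_iters Additional sweeps of the second stage; the final
#'   state of each chain after stage 2 becomes one completed dataset.
#' @param rhat_threshold Convergence threshold on the potential scale
#'   reduction factor (1.1 by convention).
#' @param pmm_donors Size of the predictive-mean-matching donor pool.
#' @param max_predictors Conditional models use at most this many predictor
#'   traits, chosen once by absolute rank correlation with the target trait.
#'   Keeps the per-sweep model fits well conditioned and fast on tables with
#'   dozens of traits.
#' @param ridge Ridge penalty (Gaussian prior precision) applied to all
#'   conditional models; guards against singular designs.
#' @return An `imputation_config` list.
#' @export
imputation_config <- function(n_chains = 4, stage1_iters = 30,
                              stage2_iters = 5, rhat_threshold = 1.1,
                              pmm_donors = 5, max_predictors = 12,
                              ridge = 1e-5) {
  stopifnot(n_chains >= 2, stage1_iters >= 1, stage2_iters >= 1,
            rhat_threshold > 1, pmm_donors >= 1, max_predictors >= 1,
            ridge >= 0)
  structure(list(n_chains = as.integer(n_chains),
                 stage1_iters = as.integer(stage1_iters),
                 stage2_iters = as.integer(stage2_iters),
                 rhat_threshold = rhat_threshold,
                 pmm_donors = as.integer(pmm_donors),
                 max_predictors = as.integer(max_predictors),
                 ridge = ridge),
            class = "imputation_config")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' With `J` chains of length `L`, `W` the mean within-chain variance and
#' `B = L * var(chain means)`,
#' `rhat = sqrt(((L - 1) / L * W + B / L) / W)`. Two conventions cover the
#' degenerate limits: identical constant chains (`W = B = 0`) give 1, and
#' divergent constant chains (`W = 0`, `B > 0`) give `Inf`.
#'
#' @param trajectories A numeric matrix (iterations in rows, chains in
#'   columns) or a list of equal-length numeric vectors, one per chain.
#' @return The potential scale reduction factor (a scalar `>= 0`).
#' @export
rhat <- function(trajectories) {
  if (is.list(trajectories)) {
    len <- lengths(trajectories)
    if (length(unique(len)) != 1L) stop("chains must have equal length")
    trajectories <- do.call(cbind, trajectories)
  }
  trajectories <- as.matrix(trajectories)
  L <- nrow(trajectories); J <- ncol(trajectories)
  if (J < 2L || L < 2L) stop("rhat needs >= 2 chains with >= 2 points each")
  W <- mean(apply(trajectories, 2L, stats::var))
  B <- L * stats::var(colMeans(trajectories))
  if (W == 0) return(if (B == 0) 1.0 else Inf)
  sqrt(((L - 1) / L * W + B / L) / W)
}

#' Impute missing phenotypes by two-stage chained equations
#'
#' Runs `n_chains` independent chains. Missing cells are initialized by
#' random draws from the observed marginal of their trait; each sweep then
#' visits the incomplete traits in order of ascending missing rate,
#' refits the trait's conditional model on the currently completed data,
#' and redraws its missing cells. Quantitative traits use a Bayesian linear
#' regression with predictive mean matching (the imputed value is always an
#' observed donor value); qualitative traits use a Bayesian
#' multinomial-logit model with weakly informative normal priors, drawing
#' categories from the posterior predictive distribution.
#'
#' Convergence is monitored per trait on the per-iteration trajectories of
#' the imputed-cell mean and standard deviation across chains: the stage-1
#' diagnostic uses the stage-1 sweeps, and the stage-2 diagnostic uses the
#' full trajectory available once stage 2 has run. Stage-2 non-convergence
#' raises a warning, never a silent pass.
#'
#' @param table A [trait_table()] with at least two traits.
#' @param config An [imputation_config()].
#' @param seed Integer master seed; per-chain sub-seeds are derived from it.
#' @return An object of class `mi_result`: a list with `completed` (one
#'   fully observed [trait_table()] per chain), `convergence` (a data.frame
#'   with per-trait, per-stage rhat of the imputed-cell mean and SD plus a
#'   `converged` flag), `config`, and bookkeeping about excluded traits.
#' @export
impute_traits <- function(table, config = imputation_config(), seed = 1) {
  stopifnot(inherits(table, "trait_table"),
            inherits(config, "imputation_config"))
  if (n_traits(table) < 2L) stop("imputation needs at least 2 traits")
  schema <- table$schema
  nm <- schema_names(schema)
  kinds <- schema_kinds(schema)
  mask <- missing_mask(table)
  n <- n_accessions(table)

  n_obs <- colSums(!mask)
  if (any(n_obs == 0))
    stop("trait(s) with no observed values cannot be imputed: ",
         paste(nm[n_obs == 0], collapse = ", "))
  distinct <- vapply(table$values, function(col)
    length(unique(col[!is.na(col)])), integer(1))
  modeled <- colSums(mask) > 0 & distinct >= 2L
  marginal_only <- colSums(mask) > 0 & distinct < 2L

  pred_sets <- select_predictors(table, config$max_predictors)
  visit <- order(colMeans(mask)[nm])          # ascending missing rate
  visit <- visit[colSums(mask)[visit] > 0]

  chain_seeds <- derive_seeds(seed, config$n_chains)
  iters_total <- config$stage1_iters + config$stage2_iters
  traj_mean <- array(NA_real_, c(iters_total, config$n_chains, length(nm)),
                     dimnames = list(NULL, NULL, nm))
  traj_sd <- traj_mean
  completed <- vector("list", config$n_chains)

  for (ch in seq_len(config$n_chains)) {
    res <- with_seed(chain_seeds[ch], {
      run_chain(table, mask, visit, modeled, marginal_only, pred_sets,
                config, iters_total)
    })
    completed[[ch]] <- res$values
    traj_mean[, ch, ] <- res$traj_mean
    traj_sd[, ch, ] <- res$traj_sd
  }

  convergence <- convergence_report(traj_mean, traj_sd, mask, nm, config)
  bad <- convergence$stage == "stage2" & !convergence$converged
  if (any(bad))
    warning("non-convergence after stage 2 for trait(s): ",
            paste(unique(convergence$trait[bad]), collapse = ", "))

  completed_tables <- lapply(completed, function(v)
    trait_table(v, schema, ids = table$ids, imputed = mask))
  structure(list(completed = completed_tables, convergence = convergence,
                 config = config,
                 trajectories = list(mean = traj_mean, sd = traj_sd),
                 marginal_only = nm[marginal_only]),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  s2 <- x$convergence[x$convergence$stage == "stage2", ]
  cat("<mi_result> ", length(x$completed), " completed datasets; ",
      sum(s2$converged), "/", nrow(s2),
      " traits converged after stage 2\n", sep = "")
  invisible(x)
}

# Static predictor sets: traits ranked by |Spearman| with the target,
# discounted by the predictor's own missing rate. Well-observed predictors
# carry real information; a mostly-imputed predictor feeds each chain its
# own guesses back and slows the mixing of the chained system.
select_predictors <- function(table, max_predictors) {
  codes <- numeric_codes(table)
  suppressWarnings(
    rho <- stats::cor(codes, use = "pairwise.complete.obs",
                      method = "spearman"))
  rho[!is.finite(rho)] <- 0
  diag(rho) <- 0
  obs_frac <- colMeans(!is.na(codes))
  score <- abs(rho) * obs_frac
  nm <- colnames(codes)
  lapply(seq_along(nm), function(j) {
    ord <- order(score[, j], decreasing = TRUE)
    nm[ord[seq_len(min(max_predictors, length(nm) - 1L))]]
  })
}

# quantitative value / qualitative category index, as a numeric matrix
numeric_codes <- function(table) {
  m <- vapply(seq_along(table$schema), function(j) {
    tr <- table$schema[[j]]
    col <- table$values[[j]]
    if (tr$kind == "quantitative") as.numeric(col)
    else as.numeric(match(col, tr$categories))
  }, numeric(n_accessions(table)))
  colnames(m) <- schema_names(table$schema)
  m
}

run_chain <- function(table, mask, visit, modeled, marginal_only, pred_sets,
                      config, iters_total) {
  schema <- table$schema
  nm <- schema_names(schema)
  kinds <- schema_kinds(schema)
  values <- table$values
  n <- nrow(values)

  # initialize missing cells from observed marginals
  for (j in seq_along(nm)) {
    mis <- mask[, j]
    if (!any(mis)) next
    obs <- values[[j]][!mis]
    values[[j]][mis] <- if (length(unique(obs)) == 1L) obs[1L]
                        else sample(obs, sum(mis), replace = TRUE)
  }

  traj_mean <- matrix(NA_real_, iters_total, length(nm))
  traj_sd <- matrix(NA_real_, iters_total, length(nm))

  for (it in seq_len(iters_total)) {
    enc <- encode_predictors(values, schema)
    for (j in visit) {
      mis <- mask[, j]
      if (marginal_only[j] || !modeled[j]) next
      X <- enc$X[, unlist(enc$cols[pred_sets[[j]]], use.names = FALSE),
                 drop = FALSE]
      y <- values[[j]]
      if (kinds[j] == "quantitative") {
        values[[j]][mis] <- draw_pmm(X[!mis, , drop = FALSE], y[!mis],
                                     X[mis, , drop = FALSE],
                                     config$pmm_donors, config$ridge)
      } else {
        res <- draw_multinomial(X[!mis, , drop = FALSE], y[!mis],
                                X[mis, , drop = FALSE],
                                schema[[j]]$categories, config$ridge)
        values[[j]][mis] <- res$draws
      }
    }
    for (j in seq_along(nm)) {
      mis <- mask[, j]
      if (!any(mis)) next
      v <- values[[j]][mis]
      imp <- if (kinds[j] == "quantitative") as.numeric(v)
             else as.numeric(match(v, schema[[j]]$categories))
      traj_mean[it, j] <- mean(imp)
      traj_sd[it, j] <- if (length(imp) >= 2L) stats::sd(imp) else 0
    }
  }
  list(values = values, traj_mean = traj_mean, traj_sd = traj_sd)
}

# encode all traits as regression predictors: quantitative standardized,
# qualitative as K-1 indicator columns (first category as reference)
encode_predictors <- function(values, schema) {
  nm <- schema_names(schema)
  cols <- vector("list", length(nm))
  names(cols) <- nm
  pieces <- vector("list", length(nm))
  pos <- 0L
  for (j in seq_along(nm)) {
    tr <- schema[[j]]
    if (tr$kind == "quantitative") {
      x <- as.numeric(values[[j]])
      s <- stats::sd(x)
      pieces[[j]] <- matrix(if (is.na(s) || s == 0) 0
                            else (x - mean(x)) / s, ncol = 1L)
    } else {
      cats <- tr$categories
      D <- matrix(0, length(values[[j]]), length(cats) - 1L)
      for (k in seq_along(cats)[-1L])
        D[, k - 1L] <- as.numeric(values[[j]] == cats[k])
      pieces[[j]] <- D
    }
    cols[[j]] <- pos + seq_len(ncol(pieces[[j]]))
    pos <- pos + ncol(pieces[[j]])
  }
  list(X = do.call(cbind, pieces), cols = cols)
}

# Bayesian linear regression + predictive mean matching (mice-style):
# draw (beta, sigma^2) from the posterior, predict the missing cases, and
# impute each with a donor drawn uniformly from the `k` observed cases whose
# fitted means are nearest the case's predicted mean.
draw_pmm <- function(X_obs, y_obs, X_mis, k, ridge) {
  X_obs <- cbind(1, X_obs); X_mis <- cbind(1, X_mis)
  p <- ncol(X_obs)
  XtX <- crossprod(X_obs) + diag(ridge * (1 + colSums(X_obs^2) / nrow(X_obs)),
                                 p)
  R <- chol(XtX)
  beta_hat <- backsolve(R, forwardsolve(t(R), crossprod(X_obs, y_obs)))
  resid <- y_obs - X_obs %*% beta_hat
  df <- max(nrow(X_obs) - p, 1L)
  sigma2 <- sum(resid^2) / stats::rchisq(1L, df)
  beta_dot <- beta_hat + sqrt(sigma2) * backsolve(R, stats::rnorm(p))
  yhat_obs <- as.numeric(X_obs %*% beta_hat)
  yhat_mis <- as.numeric(X_mis %*% beta_dot)
  vapply(yhat_mis, function(mu) {
    d <- abs(yhat_obs - mu)
    pool <- order(d)[seq_len(min(k, length(d)))]
    y_obs[pool[sample.int(length(pool), 1L)]]
  }, numeric(1))
}

# Bayesian multinomial-logit draw: the observed cases are reweighted by a
# Bayesian-bootstrap (Dirichlet) draw, and a ridge-penalized (normal-prior)
# weighted multinomial logit is fitted by Newton's method. The fitted
# parameters are one draw from the approximate posterior; categories are
# then sampled from the implied predictive distribution. Only categories
# observed in the current fit are drawn.
draw_multinomial <- function(X_obs, y_obs, X_mis, categories, ridge,
                             prior_sd = 2.5, maxit = 15L) {
  lev <- categories[categories %in% unique(y_obs)]
  if (length(lev) == 1L)
    return(list(draws = rep(lev, nrow(X_mis)), B = NULL))
  X1 <- cbind(1, scale_cols(X_obs))
  Xm <- cbind(1, scale_cols(X_mis, attr(X1, "center"), attr(X1, "scale")))
  n <- nrow(X1); p1 <- ncol(X1)
  K <- length(lev); Km1 <- K - 1L
  yi <- match(y_obs, lev)
  Y <- matrix(0, n, Km1)
  for (k in seq_len(Km1)) Y[, k] <- as.numeric(yi == k)
  B <- matrix(0, Km1, p1)
  pen <- diag(1 / prior_sd^2, p1); pen[1L, 1L] <- 1e-4
  rw <- stats::rexp(n); rw <- rw / mean(rw)       # Bayesian bootstrap
  B <- mlogit_fit(X1, Y, rw, pen, B, maxit)
  Pm <- mlogit_probs(Xm, B)
  cp <- Pm
  for (k in seq_len(K)[-1L]) cp[, k] <- cp[, k - 1L] + Pm[, k]
  u <- stats::runif(nrow(Pm)) * cp[, K]
  draws <- lev[rowSums(cp < u) + 1L]
  list(draws = draws, B = B)
}

# Newton solver for the ridge-penalized, case-weighted multinomial logit
# (reference category last); returns the (K-1) x p coefficient matrix
mlogit_fit <- function(X1, Y, rw, pen, B, maxit = 15L) {
  p1 <- ncol(X1)
  Km1 <- ncol(Y)
  for (it in seq_len(maxit)) {
    P <- mlogit_probs(X1, B)
    Pk <- P[, seq_len(Km1), drop = FALSE]
    G <- crossprod(X1, rw * (Y - Pk)) - pen %*% t(B)
    H <- matrix(0, Km1 * p1, Km1 * p1)
    for (a in seq_len(Km1)) for (b in seq_len(a)) {
      w <- if (a == b) rw * Pk[, a] * (1 - Pk[, a])
           else -rw * Pk[, a] * Pk[, b]
      blk <- crossprod(X1 * w, X1)
      if (a == b) blk <- blk + pen
      ia <- ((a - 1L) * p1 + 1L):(a * p1)
      ib <- ((b - 1L) * p1 + 1L):(b * p1)
      H[ia, ib] <- blk; H[ib, ia] <- t(blk)
    }
    step <- tryCatch(solve(H, as.vector(G)), error = function(e) NULL)
    if (is.null(step)) break
    if (max(abs(step)) > 20) step <- step * 20 / max(abs(step))
    B <- B + t(matrix(step, p1, Km1))
    if (max(abs(step)) < 1e-3) break
  }
  B
}

mlogit_probs <- function(X, B) {
  eta <- cbind(X %*% t(B), 0)
  eta <- eta - eta[cbind(seq_len(nrow(eta)), max.col(eta))]
  E <- exp(eta)
  E / rowSums(E)
}

scale_cols <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) {
    center <- colMeans(X)
    scale <- apply(X, 2L, stats::sd)
    scale[scale == 0 | is.na(scale)] <- 1
  }
  out <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

convergence_report <- function(traj_mean, traj_sd, mask, nm, config) {
  # at each checkpoint the diagnostic discards the first half of the
  # trajectory as warm-up, the usual Gelman-Rubin practice
  L1 <- config$stage1_iters
  L2 <- config$stage1_iters + config$stage2_iters
  s1 <- seq.int(floor(L1 / 2) + 1L, L1)
  s2 <- seq.int(floor(L2 / 2) + 1L, L2)
  rows <- list()
  for (stage in c("stage1", "stage2")) {
    idx <- if (stage == "stage1") s1 else s2
    for (j in seq_along(nm)) {
      if (!any(mask[, j])) {
        rows[[length(rows) + 1L]] <- data.frame(
          trait = nm[j], stage = stage, rhat_mean = 1, rhat_sd = 1,
          n_missing = 0L, converged = TRUE)
        next
      }
      rm_ <- rhat(traj_mean[idx, , j])
      rs_ <- if (all(traj_sd[idx, , j] == 0)) 1 else rhat(traj_sd[idx, , j])
      rows[[length(rows) + 1L]] <- data.frame(
        trait = nm[j], stage = stage, rhat_mean = rm_, rhat_sd = rs_,
        n_missing = sum(mask[, j]),
        converged = rm_ < config$rhat_threshold &
                    rs_ < config$rhat_threshold)
    }
  }
  do.call(rbind, rows)
}

#' Pool completed datasets into a single table
#'
#' Quantitative imputed cells are pooled by the arithmetic mean across the
#' completed datasets; qualitative imputed cells by majority vote, with
#' ties broken first by the higher observed marginal frequency of the tied
#' categories and then by schema category order. Observed cells pass
#' through untouched, and the returned table marks every pooled cell as
#' imputed.
#'
#' @param result An `mi_result` from [impute_traits()], or a plain list of
#'   completed [trait_table()]s.
#' @param original The original (incomplete) [trait_table()]; used for the
#'   missingness mask and observed marginals.
#' @return A fully observed [trait_table()] with provenance marks.
#' @export
pool_imputations <- function(result, original) {
  members <- if (inherits(result, "mi_result")) result$completed else result
  stopifnot(length(members) >= 1L, inherits(original, "trait_table"))
  mask <- missing_mask(original)
  schema <- original$schema
  values <- original$values
  for (j in seq_along(schema)) {
    mis <- which(mask[, j])
    if (!length(mis)) next
    draws <- vapply(members, function(m) m$values[[j]][mis],
                    if (schema[[j]]$kind == "quantitative")
                      numeric(length(mis)) else character(length(mis)))
    draws <- matrix(draws, nrow = length(mis))
    if (schema[[j]]$kind == "quantitative") {
      values[[j]][mis] <- rowMeans(draws)
    } else {
      cats <- schema[[j]]$categories
      obs_freq <- table(factor(original$values[[j]][!mask[, j]],
                               levels = cats))
      values[[j]][mis] <- apply(draws, 1L, function(d) {
        cnt <- table(factor(d, levels = cats))
        top <- names(cnt)[cnt == max(cnt)]
        if (length(top) == 1L) return(top)
        top <- top[obs_freq[top] == max(obs_freq[top])]
        top[1L]                                  # schema order breaks ties
      })
    }
  }
  trait_table(values, schema, ids = original$ids, imputed = mask)
}
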