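#' Fit a latent profile model (diagonal Gaussian mixture) by EM
#'
#' Latent class analysis with continuous indicators: a k-component Gaussian
#' mixture with diagonal covariances (local independence) fitted by
#' expectation-maximisation on standardised variables, taking the best of
#' `n_init` seeded random restarts by log-likelihood. A variance floor guards
#' against component collapse (collapsing restarts are counted). The
#' log-likelihood is checked to be non-decreasing across iterations on every
#' fit.
#'
#' @param X numeric matrix or data frame of indicators (no missing values).
#' @param k number of components (`n > k` required).
#' @param n_init number of random restarts (default 20).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter maximum EM iterations per restart (default 500).
#' @param seed RNG seed; restarts use seeds derived from it.
#' @param var_floor minimum variance on the standardised scale
#'   (default 1e-4).
#' @return object of class `lpa`: mixing weights, per-component means and
#'   SDs on both the standardised and original scales, log-likelihood, AIC,
#'   BIC, responsibilities, hard labels (argmax responsibility), and the
#'   standardisation constants.
#' @export
fit_mixture <- function(X, k, n_init = 20, tol = 1e-6, max_iter = 500,
                        seed = 1, var_floor = 1e-4) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must not contain missing values", call. = FALSE)
  n <- nrow(X)
  d <- ncol(X)
  stopifnot(n > k, k >= 1)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, `/`)

  Z2 <- Z^2
  em_once <- function(init_seed) {
    with_seed(init_seed, {
      mu <- Z[sample.int(n, k), , drop = FALSE]
      sg <- matrix(1, k, d)
      pi_k <- rep(1 / k, k)
      ll_old <- -Inf
      ll_trace <- numeric(0)
      collapsed <- 0L
      for (it in seq_len(max_iter)) {
        # log N(x; mu_j, diag(sg_j^2)) via the quadratic expansion
        # -0.5 * (x^2/s2 - 2 x mu/s2 + mu^2/s2), one matrix product per term
        inv_s2 <- 1 / sg^2                       # k x d
        const <- log(pi_k) - rowSums(log(sg)) -
          0.5 * rowSums(mu^2 * inv_s2) - d / 2 * log(2 * pi)
        logdens <- tcrossprod(Z2, -0.5 * inv_s2) +
          tcrossprod(Z, mu * inv_s2)
        logdens <- sweep(logdens, 2, const, `+`)
        mx <- logdens[cbind(seq_len(n),
                            max.col(logdens, ties.method = "first"))]
        lse <- mx + log(rowSums(exp(logdens - mx)))
        ll <- sum(lse)
        resp <- exp(logdens - lse)
        nk <- colSums(resp)
        if (any(nk < 1e-8)) {
          collapsed <- collapsed + 1L
          nk <- pmax(nk, 1e-8)
        }
        pi_k <- nk / n
        mu <- crossprod(resp, Z) / nk
        ex2 <- crossprod(resp, Z2) / nk
        sg <- sqrt(pmax(ex2 - mu^2, var_floor))
        ll_trace <- c(ll_trace, ll)
        if (is.finite(ll_old) && ll - ll_old < tol * abs(ll)) break
        ll_old <- ll
      }
      list(pi = pi_k, mu = mu, sigma = sg, loglik = ll,
           ll_trace = ll_trace, resp = resp, collapsed = collapsed)
    })
  }

  best <- NULL
  n_collapsed <- 0L
  for (i in seq_len(n_init)) {
    fit <- em_once(seed * 1000L + i)
    n_collapsed <- n_collapsed + fit$collapsed
    if (diff(range(diff(fit$ll_trace))) > 0 &&
        any(diff(fit$ll_trace) < -1e-6 * abs(fit$loglik))) {
      stop("EM log-likelihood decreased; numerical failure", call. = FALSE)
    }
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  n_par <- (k - 1) + 2 * k * d
  labels <- max.col(best$resp, ties.method = "first")
  mu_orig <- sweep(sweep(best$mu, 2, scl, `*`), 2, ctr, `+`)
  sg_orig <- sweep(best$sigma, 2, scl, `*`)
  colnames(mu_orig) <- colnames(sg_orig) <- colnames(X)
  structure(list(k = k, weights = best$pi, means = mu_orig, sds = sg_orig,
                 means_std = best$mu, sds_std = best$sigma,
                 loglik = best$loglik,
                 aic = 2 * n_par - 2 * best$loglik,
                 bic = n_par * log(n) - 2 * best$loglik,
                 n_par = n_par, responsibilities = best$resp,
                 labels = labels, ll_trace = best$ll_trace,
                 n_collapsed_restarts = n_collapsed,
                 variables = colnames(X), center = ctr, scale = scl,
                 n = n),
            class = "lpa")
}

#' @export
print.lpa <- function(x, ...) {
  cat(sprintf("Latent profile model: %d components, %d variables, n = %d\n",
              x$k, length(x$variables), x$n))
  cat(sprintf("  logLik = %.1f, AIC = %.1f, BIC = %.1f\n",
              x$loglik, x$aic, x$bic))
  cat("  mixing weights:", paste(sprintf("%.3f", x$weights), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
summary.lpa <- function(object, ...) {
  print(object)
  cat("\nComponent means (original scale):\n")
  print(round(object$means, 2))
  invisible(object)
}

#' @export
logLik.lpa <- function(object, ...) {
  structure(object$loglik, df = object$n_par, nobs = object$n,
            class = "logLik")
}

#' Posterior responsibilities or hard labels for new data
#'
#' @param object a fitted [fit_mixture()] model.
#' @param newdata matrix/data frame on the original variable scale; defaults
#'   to the training responsibilities.
#' @param type `"class"` for hard labels, `"prob"` for responsibilities.
#' @param ... unused.
#' @export
predict.lpa <- function(object, newdata = NULL,
                        type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    resp <- object$responsibilities
  } else {
    Z <- sweep(sweep(as.matrix(newdata), 2, object$center), 2,
               object$scale, `/`)
    n <- nrow(Z)
    d <- ncol(Z)
    logdens <- matrix(0, n, object$k)
    for (j in seq_len(object$k)) {
      logdens[, j] <- log(object$weights[j]) +
        rowSums(dnorm(Z, matrix(object$means_std[j, ], n, d, byrow = TRUE),
                      matrix(object$sds_std[j, ], n, d, byrow = TRUE),
                      log = TRUE))
    }
    mx <- apply(logdens, 1, max)
    resp <- exp(logdens - (mx + log(rowSums(exp(logdens - mx)))))
  }
  if (type == "class") max.col(resp, ties.method = "first") else resp
}

#' Select the number of latent profiles by a BIC elbow
#'
#' Fits mixtures over `k_range` (a 1-component fit is always included as the
#' elbow baseline) and returns the full AIC/BIC curves plus the elbow
#' choice: the smallest k whose BIC improvement from k to k+1 falls below
#' `frac` (default 5%) of the 1-to-2-component improvement. An explicit
#' `override` bypasses the rule while still returning the curves.
#'
#' @param X indicator matrix.
#' @param k_range candidate component counts (default 2:8).
#' @param n_init,seed,... passed to [fit_mixture()].
#' @param frac elbow fraction (default 0.05).
#' @param override force this k.
#' @return list with `k`, `criteria` (data frame k/AIC/BIC/logLik/n_par),
#'   and `fits` (the fitted models, named by k).
#' @export
select_k <- function(X, k_range = 2:8, n_init = 20, seed = 1, frac = 0.05,
                     override = NULL, ...) {
  ks <- sort(unique(c(1L, as.integer(k_range))))
  fits <- lapply(ks, function(k) {
    fit_mixture(X, k, n_init = if (k == 1) 1 else n_init, seed = seed, ...)
  })
  names(fits) <- ks
  crit <- data.frame(k = ks,
                     logLik = vapply(fits, `[[`, numeric(1), "loglik"),
                     n_par = vapply(fits, `[[`, numeric(1), "n_par"),
                     AIC = vapply(fits, `[[`, numeric(1), "aic"),
                     BIC = vapply(fits, `[[`, numeric(1), "bic"))
  if (!is.null(override)) {
    return(list(k = as.integer(override), criteria = crit, fits = fits,
                rule = "override"))
  }
  gain <- -diff(crit$BIC)           # improvement from k to k+1
  baseline <- gain[1]               # 1 -> 2 components
  chosen <- NA_integer_
  for (i in seq_along(gain)) {
    if (crit$k[i] >= min(k_range) && gain[i] < frac * baseline) {
      chosen <- crit$k[i]
      break
    }
  }
  if (is.na(chosen)) chosen <- max(ks)
  list(k = chosen, criteria = crit, fits = fits, rule = "bic_elbow")
}

#' Rule-based subtype labels for a five-profile model
#'
#' Assigns the field's subgroup nomenclature to the components of a fitted
#' 5-profile model from their mean profiles: MOD is the component with the
#' highest mean BMI; SIRD the highest mean triglycerides; MARD the highest
#' mean age among the remainder. For the clinical model the highest
#' remaining HDL is MD and the residual component CUD; for the integrated
#' model the next-highest triglycerides is IRD and the residual pSIDD (which
#' is checked, with a warning flag, to carry the highest mean PRS of the
#' final two).
#'
#' @param model a fitted [fit_mixture()] with k = 5 whose variables include
#'   `bmi`, `tg`, `age`, and `hdl` (clinical) or `prs` (integrated).
#' @param model_kind `"clinical"` or `"integrated"`.
#' @return list with `labels` (component index -> subtype name),
#'   `assignments` (per-individual subtype), and `unresolved` flag when two
#'   rules select the same component.
#' @export
label_clusters <- function(model, model_kind = c("clinical", "integrated")) {
  model_kind <- match.arg(model_kind)
  if (model$k != 5) stop("subtype labelling requires a 5-component model",
                         call. = FALSE)
  mu <- model$means
  need <- c("bmi", "tg", "age",
            if (model_kind == "clinical") "hdl" else "prs")
  if (!all(need %in% colnames(mu))) {
    stop("model variables must include: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lab <- rep(NA_character_, 5)
  m_mod <- which.max(mu[, "bmi"])
  m_sird <- which.max(mu[, "tg"])
  unresolved <- m_mod == m_sird
  if (!unresolved) {
    lab[m_mod] <- "MOD"
    lab[m_sird] <- "SIRD"
    rem <- which(is.na(lab))
    m_mard <- rem[which.max(mu[rem, "age"])]
    lab[m_mard] <- "MARD"
    rem <- which(is.na(lab))
    if (model_kind == "clinical") {
      m_md <- rem[which.max(mu[rem, "hdl"])]
      lab[m_md] <- "MD"
      lab[which(is.na(lab))] <- "CUD"
    } else {
      m_ird <- rem[which.max(mu[rem, "tg"])]
      lab[m_ird] <- "IRD"
      m_psidd <- which(is.na(lab))
      lab[m_psidd] <- "pSIDD"
      if (mu[m_psidd, "prs"] < mu[m_ird, "prs"]) {
        warning("pSIDD component does not carry the highest PRS of the ",
                "final two components")
      }
    }
  }
  list(labels = lab,
       assignments = if (unresolved) NULL else lab[model$labels],
       unresolved = unresolved)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same
#' individuals; 1 means identical partitions, 0 the expectation under random
#' labelling.
#'
#' @param a,b cluster label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
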