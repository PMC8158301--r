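# Survival machinery: Kaplan-Meier product-limit curves, the k-group
# log-rank test with full hypergeometric variance, Cox proportional-hazards
# fitting by Newton-Raphson on the Breslow partial likelihood, and the
# best-separation (minimal log-rank p) cutpoint search for score
# stratification.

check_clinical <- function(clinical) {
  stopifnot(is.data.frame(clinical))
  need <- c("sample", "time_months", "event")
  missing <- setdiff(need, names(clinical))
  if (length(missing))
    stop("clinical table lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(clinical$sample))
    stop("duplicate sample ids in clinical table")
  if (any(clinical$time_months <= 0)) stop("survival times must be positive")
  if (!all(clinical$event %in% c(0, 1))) stop("event must be 0/1")
  invisible(clinical)
}

#' Kaplan-Meier product-limit curve
#'
#' @param time,event survival times and 0/1 event flags.
#' @return data.frame (time, n_risk, n_event, n_censor, surv), one row per
#'   distinct observed time; `surv` is the step value just after that time.
#' @export
km_curve <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ut <- unique(time)
  n <- length(time)
  d <- rowsum(event, time)[, 1L]
  c_ <- rowsum(1 - event, time)[, 1L]
  at_risk <- n - c(0, cumsum(d + c_)[-length(ut)])
  surv <- cumprod(1 - d / at_risk)
  data.frame(time = ut, n_risk = at_risk, n_event = as.numeric(d),
             n_censor = as.numeric(c_), surv = surv, row.names = NULL)
}

#' Median survival time from a KM curve
#'
#' First observed event time at which the KM estimate drops to 0.5 or below
#' (step convention, no interpolation); NA if the curve never reaches 0.5.
#'
#' @param curve a [km_curve()] result.
#' @return a single time (months) or NA.
#' @export
km_median <- function(curve) {
  hit <- which(curve$surv <= 0.5 & curve$n_event > 0)
  if (!length(hit)) return(NA_real_)
  curve$time[hit[1L]]
}

#' K-group log-rank test with Kaplan-Meier curves
#'
#' Standard log-rank chi-square on k-1 degrees of freedom using the full
#' hypergeometric covariance of the per-group observed-minus-expected event
#' counts.
#'
#' @param groups named group label per sample.
#' @param clinical clinical table (sample, time_months, event, ...).
#' @return list: `curves` (per-group KM data.frames), `observed`,
#'   `expected`, `chisq`, `df`, `p`.
#' @export
km_logrank <- function(groups, clinical) {
  check_clinical(clinical)
  if (is.null(names(groups))) stop("groups must be named by sample")
  missing <- setdiff(clinical$sample, names(groups))
  if (length(missing))
    stop("ungrouped samples: ", paste(missing, collapse = ", "))
  g <- factor(as.character(groups[clinical$sample]))
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(tabulate(g) == 0L)) stop("a group has zero samples")
  if (sum(clinical$event) < 1L) stop("need at least one event")

  time <- clinical$time_months; event <- clinical$event
  k <- nlevels(g)
  ev_times <- sort(unique(time[event == 1]))
  O <- tabulate(g[event == 1], nbins = k)
  E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ev_times) {
    at <- time >= t
    n_t <- sum(at)
    n_j <- tabulate(g[at], nbins = k)
    d_t <- sum(event == 1 & time == t)
    d_j <- tabulate(g[event == 1 & time == t], nbins = k)
    E <- E + d_t * n_j / n_t
    if (n_t > 1) {
      frac <- n_j / n_t
      V <- V + d_t * (n_t - d_t) / (n_t - 1) *
        (diag(frac, k) - tcrossprod(frac))
    }
  }
  U <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  chisq <- if (all(abs(U) < 1e-12)) 0 else {
    Vinv <- tryCatch(solve(Vk), error = function(e) {
      s <- svd(Vk); pos <- s$d > max(s$d) * 1e-10
      s$v[, pos, drop = FALSE] %*% diag(1 / s$d[pos], sum(pos)) %*%
        t(s$u[, pos, drop = FALSE])
    })
    drop(t(U) %*% Vinv %*% U)
  }
  p <- pchisq(chisq, df = k - 1, lower.tail = FALSE)
  curves <- lapply(levels(g), function(lv) {
    sel <- g == lv
    km_curve(time[sel], event[sel])
  })
  names(curves) <- levels(g)
  list(curves = curves, observed = O, expected = E, chisq = chisq,
       df = k - 1L, p = p)
}

#' Cox proportional-hazards fit (Breslow ties, Newton-Raphson)
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson with
#' step-halving until the gradient norm falls below `tol`; Wald confidence
#' intervals and p-values come from the inverse observed information.
#' Constant covariates are dropped with a warning.
#'
#' @param covariates samples x variables numeric matrix or data.frame with
#'   rownames (or a `sample` column) matching the clinical table.
#' @param clinical clinical table (sample, time_months, event, ...).
#' @param adjust optional character vector of clinical column names appended
#'   as additional covariates.
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @return a `cox_fit`: list with `coefficients` data.frame (term, coef, hr,
#'   hr_lower, hr_upper, se, z, p), `loglik` (initial, final), `iterations`,
#'   `converged`, `gradient_norm`, `vcov`, `n`, `n_event`.
#' @export
cox_fit <- function(covariates, clinical, adjust = NULL, tol = 1e-8,
                    max_iter = 100L) {
  check_clinical(clinical)
  x <- covariates
  if (is.data.frame(x)) {
    if ("sample" %in% names(x)) {
      rownames(x) <- x$sample
      x$sample <- NULL
    }
    x <- as.matrix(x)
  }
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L,
                                   dimnames = list(names(x), "score"))
  if (is.null(rownames(x))) stop("covariates must be keyed by sample id")
  missing <- setdiff(clinical$sample, rownames(x))
  if (length(missing))
    stop("covariates missing for samples: ", paste(missing, collapse = ", "))
  x <- x[clinical$sample, , drop = FALSE]
  if (length(adjust)) {
    bad <- setdiff(adjust, names(clinical))
    if (length(bad)) stop("unknown adjust columns: ", paste(bad, collapse = ", "))
    x <- cbind(x, as.matrix(clinical[, adjust, drop = FALSE]))
  }
  keep <- apply(x, 2L, function(v) sd(v) > 0)
  if (any(!keep)) {
    warning("dropping constant covariates: ",
            paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  p <- ncol(x)
  if (p == 0L) stop("no usable covariates")
  n_event <- sum(clinical$event)
  if (n_event < p) stop("fewer events than covariates")

  time <- clinical$time_months; event <- clinical$event
  n <- length(time)
  ut <- sort(unique(time), decreasing = TRUE)   # walk risk sets downward

  breslow <- function(beta) {
    eta <- drop(x %*% beta)
    w <- exp(eta)
    ll <- 0; grad <- numeric(p); hess <- matrix(0, p, p)
    S0 <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
    for (t in ut) {
      at <- which(time == t)
      for (i in at) {
        S0 <- S0 + w[i]
        S1 <- S1 + w[i] * x[i, ]
        S2 <- S2 + w[i] * tcrossprod(x[i, ])
      }
      ev <- at[event[at] == 1]
      if (length(ev)) {
        d <- length(ev)
        xbar <- S1 / S0
        ll <- ll + sum(eta[ev]) - d * log(S0)
        grad <- grad + colSums(x[ev, , drop = FALSE]) - d * xbar
        hess <- hess - d * (S2 / S0 - tcrossprod(xbar))
      }
    }
    list(ll = ll, grad = grad, hess = hess)
  }

  beta <- numeric(p)
  st <- breslow(beta)
  ll0 <- st$ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    gnorm <- sqrt(sum(st$grad^2))
    if (gnorm < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(st$hess, -st$grad),
                     error = function(e) stop("singular Hessian in Cox fit"))
    halve <- 0L
    repeat {
      cand <- beta + step
      st_new <- breslow(cand)
      # tolerate rounding-scale decreases so the last Newton step near the
      # optimum is not rejected by the line search
      if (is.finite(st_new$ll) &&
          (st_new$ll >= st$ll - 1e-10 * (abs(st$ll) + 1) || halve >= 20L))
        break
      step <- step / 2
      halve <- halve + 1L
    }
    beta <- cand
    st <- st_new
  }
  gnorm <- sqrt(sum(st$grad^2))
  if (gnorm < tol) converged <- TRUE
  if (!converged)
    stop(sprintf(
      "Cox fit did not converge in %d iterations (gradient norm %.3g, loglik %.6f)",
      max_iter, gnorm, st$ll))

  vcov <- solve(-st$hess)
  se <- sqrt(diag(vcov))
  z <- beta / se
  coefs <- data.frame(
    term = colnames(x), coef = beta, hr = exp(beta),
    hr_lower = exp(beta - 1.959963984540054 * se),
    hr_upper = exp(beta + 1.959963984540054 * se),
    se = se, z = z, p = 2 * pnorm(abs(z), lower.tail = FALSE),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, loglik = c(ll0, st$ll),
                 iterations = iter, converged = converged,
                 gradient_norm = gnorm, vcov = vcov, n = n,
                 n_event = n_event),
            class = "cox_fit")
}

# Fast two-group log-rank p-value used by the cutpoint scan. Takes data
# pre-sorted by time; `g` marks group membership in sorted order.
logrank2_p <- function(time_sorted, event_sorted, tgroup, g) {
  n1 <- rev(cumsum(rev(as.numeric(g))))       # group-1 members still at risk
  nt <- rev(cumsum(rev(rep(1, length(g)))))
  first <- !duplicated(tgroup)
  n1_t <- n1[first]; n_t <- nt[first]
  d_t <- rowsum(event_sorted, tgroup, reorder = FALSE)[, 1L]
  d1_t <- rowsum(event_sorted * g, tgroup, reorder = FALSE)[, 1L]
  use <- d_t > 0
  n1_t <- n1_t[use]; n_t <- n_t[use]; d_t <- d_t[use]; d1_t <- d1_t[use]
  E1 <- d_t * n1_t / n_t
  ok <- n_t > 1
  V <- sum((d_t * (n_t - d_t) * n1_t * (n_t - n1_t) /
              (n_t^2 * (n_t - 1)))[ok])
  U <- sum(d1_t - E1)
  if (V <= 0) return(1)
  pchisq(U^2 / V, df = 1, lower.tail = FALSE)
}

#' Best-separation survival cutpoint for a continuous score
#'
#' Scans the midpoints of sorted unique score values, keeps candidates
#' leaving at least `min_prop` of the cohort on each side, and returns the
#' cutoff minimizing the two-group log-rank p-value (ties broken toward the
#' lower cutoff). The minimal p is returned with `selection_biased = TRUE`:
#' it is an optimized statistic, not a nominal test level.
#'
#' @param score named per-sample numeric score.
#' @param clinical clinical table (sample, time_months, event, ...).
#' @param min_prop minimum fraction of samples on each side of the cut.
#' @return list: `cutoff`, `labels` (named high/low factor), `p`,
#'   `selection_biased` (always TRUE), `candidates` (data.frame cutoff, p).
#' @export
best_cutpoint <- function(score, clinical, min_prop = 0.1) {
  check_clinical(clinical)
  if (is.null(names(score))) stop("score must be named by sample")
  missing <- setdiff(clinical$sample, names(score))
  if (length(missing))
    stop("score missing for samples: ", paste(missing, collapse = ", "))
  if (sum(clinical$event) < 20L)
    stop("best_cutpoint requires >= 20 samples with events")
  s <- score[clinical$sample]
  n <- length(s)
  min_side <- max(1L, ceiling(min_prop * n))
  us <- sort(unique(s))
  if (length(us) < 2L) stop("score is constant")
  mids <- (head(us, -1) + us[-1]) / 2
  n_below <- vapply(mids, function(m) sum(s <= m), 0L)
  ok <- n_below >= min_side & (n - n_below) >= min_side
  if (!any(ok)) stop("no candidate cutoff satisfies min_prop = ", min_prop)
  mids <- mids[ok]

  ord <- order(clinical$time_months)
  t_s <- clinical$time_months[ord]
  e_s <- clinical$event[ord]
  tg <- cumsum(!duplicated(t_s))
  s_s <- s[ord]
  pvals <- vapply(mids, function(m)
    logrank2_p(t_s, e_s, tg, s_s > m), 0)
  best <- which.min(pvals)                       # which.min takes first tie
  cutoff <- mids[best]
  labels <- factor(ifelse(s > cutoff, "high", "low"),
                   levels = c("low", "high"))
  names(labels) <- names(s)
  list(cutoff = cutoff, labels = labels, p = pvals[best],
       selection_biased = TRUE,
       candidates = data.frame(cutoff = mids, p = pvals, row.names = NULL))
}
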