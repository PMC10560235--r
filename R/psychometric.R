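#' Fit the psychometric logistic model
#'
#' Logistic model of /p/ responses with fixed effects
#' `response ~ (VOT + Bias) * Disconnection`, with VOT as the centered step
#' number (1..6 centered), Bias coded +/- 0.5 (/p/ vs /b/) and
#' Disconnection coded +/- 0.5 (post vs pre). Standard errors are obtained
#' by a cluster bootstrap over word pairs (resampling whole word-pair
#' clusters with replacement), which accounts for the word-pair grouping
#' the study design induces; Wald Z statistics use the bootstrap SEs.
#'
#' @param responses response table from [simulate_behavior()] (or any data
#'   frame with `response`, `vot_step`, `bias`, `phase` and the grouping
#'   column).
#' @param grouping name of the clustering column (default `"word_pair"`,
#'   the random factor of the study design).
#' @param se_method `"bootstrap"` (cluster bootstrap over the grouping
#'   factor, the default) or `"model"` (model-based Fisher-information
#'   SEs, which ignore the grouping structure).
#' @param n_boot number of cluster bootstrap resamples (default 2000).
#' @param seed integer seed for the bootstrap.
#' @return Object of class `psychometric_fit`: data frame `coefficients`
#'   (`term`, `estimate`, `se`, `z`, `p`), `n_boot`, `n_trials`,
#'   `converged`, `separation` flag.
#' @export
fit_psychometric <- function(responses, grouping = "word_pair",
                             se_method = c("bootstrap", "model"),
                             n_boot = 2000, seed = 1) {
  se_method <- match.arg(se_method)
  dat <- as.data.frame(responses)
  need <- c("response", "vot_step", "bias", "phase", grouping)
  if (!all(need %in% names(dat))) {
    stopf("responses must have columns %s", paste(need, collapse = ", "))
  }
  dat <- dat[!is.na(dat$response), ]
  steps <- sort(unique(dat$vot_step))
  X <- psymat(dat, center = mean(steps))
  y <- dat$response
  fit <- fit_logistic(X, y)
  if (fit$separation) {
    warnf("quasi-separation detected; ridge-penalized fit used")
  }
  wps <- unique(dat[[grouping]])
  if (se_method == "model" || length(wps) < 2L) {
    if (se_method == "bootstrap") {
      warnf("fewer than 2 clusters; falling back to model-based SEs")
    }
    se <- fit$se
  } else {
    idx_by_wp <- split(seq_len(nrow(dat)), dat[[grouping]])
    boot <- with_seed(seed, {
      B <- matrix(NA_real_, n_boot, ncol(X))
      for (b in seq_len(n_boot)) {
        take <- unlist(idx_by_wp[sample.int(length(wps), replace = TRUE)],
                       use.names = FALSE)
        bf <- tryCatch(fit_logistic(X[take, , drop = FALSE], y[take]),
                       error = function(e) NULL)
        if (!is.null(bf)) B[b, ] <- bf$beta
      }
      B
    })
    ok <- stats::complete.cases(boot)
    ## small-cluster correction: the plug-in bootstrap variance is biased
    ## down by (G-1)/G when only G clusters are resampled
    G <- length(wps)
    se <- apply(boot[ok, , drop = FALSE], 2, stats::sd) * sqrt(G / (G - 1))
  }
  z <- fit$beta / se
  coefs <- data.frame(term = colnames(X), estimate = fit$beta, se = se,
                      z = z, p = 2 * stats::pnorm(-abs(z)),
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, n_boot = n_boot,
                 n_trials = nrow(dat), converged = fit$converged,
                 separation = fit$separation, seed = seed),
            class = "psychometric_fit")
}

## design matrix for the (VOT + Bias) * Disconnection fixed-effects model
psymat <- function(dat, center) {
  vot_c <- dat$vot_step - center
  bias_c <- ifelse(dat$bias == "p", 0.5, -0.5)
  disc_c <- ifelse(dat$phase == "post", 0.5, -0.5)
  cbind(intercept = 1, vot = vot_c, bias = bias_c, disconnection = disc_c,
        vot_disc = vot_c * disc_c, bias_disc = bias_c * disc_c)
}

## plain logistic fit via glm.fit, with a small-ridge IRLS fallback when the
## fit is separated (unbounded coefficients)
fit_logistic <- function(X, y) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial()))
  beta <- fit$coefficients
  separation <- !fit$converged || any(!is.finite(beta)) ||
    max(abs(beta), na.rm = TRUE) > 15
  if (separation) {
    beta <- ridge_logistic(X, y, lambda = 1e-2)
    fit$converged <- TRUE
  }
  ## model-based covariance for the no-cluster fallback
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  XtWX <- crossprod(X * w, X)
  se <- sqrt(diag(solve(XtWX + diag(1e-10, ncol(X)))))
  list(beta = beta, se = se, converged = fit$converged,
       separation = separation)
}

ridge_logistic <- function(X, y, lambda = 1e-2, max_iter = 100L) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new <- solve(crossprod(X * w, X) + diag(lambda, ncol(X)),
                 crossprod(X * w, z))
    if (max(abs(new - beta)) < 1e-8) {
      beta <- drop(new)
      break
    }
    beta <- drop(new)
  }
  stats::setNames(beta, colnames(X))
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("Psychometric logistic fit (%d trials, %d cluster bootstrap resamples):\n",
              x$n_trials, x$n_boot))
  print(transform(x$coefficients, estimate = round(estimate, 4),
                  se = round(se, 4), z = round(z, 3),
                  p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' Psychometric curves: /p/-response proportions per cell
#'
#' Cell proportions of /p/ responses per (bias, VOT step, phase), with the
#' binomial standard error of the mean. Cells without trials are reported
#' as missing rather than zero.
#'
#' @param responses response table (see [fit_psychometric()]).
#' @return Data frame `bias`, `vot_step`, `phase`, `n`, `p_resp`, `sem`.
#' @export
psychometric_curves <- function(responses) {
  dat <- as.data.frame(responses)
  dat <- dat[!is.na(dat$response), ]
  cells <- expand.grid(bias = sort(unique(dat$bias)),
                       vot_step = sort(unique(dat$vot_step)),
                       phase = sort(unique(dat$phase)),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- dat$bias == cells$bias[i] & dat$vot_step == cells$vot_step[i] &
      dat$phase == cells$phase[i]
    n <- sum(sel)
    if (n == 0L) {
      data.frame(cells[i, ], n = 0L, p_resp = NA_real_, sem = NA_real_)
    } else {
      pr <- mean(dat$response[sel])
      data.frame(cells[i, ], n = n, p_resp = pr,
                 sem = sqrt(pr * (1 - pr) / n))
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Reliable change index
#'
#' Jacobson-Truax reliable change index for a pre/post score pair:
#' `RCI = (post - pre) / (sd * sqrt(2) * sqrt(1 - r))`, where `sd` is the
#' population (norm) standard deviation of the test and `r` its test-retest
#' reliability. |RCI| >= 1.96 flags a significant change between
#' timepoints.
#'
#' @param pre,post scores (vectors of equal length).
#' @param r test-retest reliability in (0, 1) (recycled).
#' @param sd norm standard deviation (> 0, recycled).
#' @param labels optional test labels.
#' @return Data frame `test`, `pre`, `post`, `r`, `sd`, `rci`,
#'   `significant`.
#' @export
reliable_change_index <- function(pre, post, r, sd, labels = NULL) {
  if (length(pre) != length(post)) stopf("pre and post must have equal length")
  r <- rep_len(r, length(pre)); sd <- rep_len(sd, length(pre))
  if (any(r <= 0 | r >= 1)) stopf("reliability r must lie in (0, 1)")
  if (any(sd <= 0)) stopf("sd must be positive")
  rci <- (post - pre) / (sd * sqrt(2) * sqrt(1 - r))
  data.frame(test = labels %||% paste0("test", seq_along(pre)),
             pre = pre, post = post, r = r, sd = sd, rci = rci,
             significant = abs(rci) >= 1.96)
}
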