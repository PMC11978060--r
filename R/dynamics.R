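#' Fit cubic polynomial time-course models per promoter
#'
#' Ordinary least squares of absolute activity on polynomial terms of
#' developmental time (intercept + t + t^2 + t^3 by default), fitted
#' independently per promoter within one organ. Time is standardized to
#' zero mean and unit variance before polynomial expansion for numerical
#' conditioning; R-squared and the model F-test are invariant to this
#' affine rescaling. Missing activities are dropped pairwise; promoters
#' observed in fewer than `minObsFrac` of the samples, or with fewer
#' distinct times than `degree + 1`, are skipped with a recorded reason.
#'
#' @param x numeric matrix, promoters x samples (absolute activity of one
#'   organ), with promoter identifiers as row names.
#' @param times numeric developmental time per sample (ordinal stage index).
#' @param degree polynomial degree (default 3).
#' @param minObsFrac minimum fraction of samples with data (default 0.7).
#' @return data.frame with one row per promoter: `promoter_id`, `n_obs`,
#'   coefficients `beta0`..`beta<degree>` (on the standardized time scale),
#'   `r_squared`, `p_value` (F-test of the full model against
#'   intercept-only), fitted values at the earliest and latest observed
#'   time (`fitted_first`, `fitted_last`), and `skipped` (`NA` or reason).
#' @export
fitPromoterTrends <- function(x, times, degree = 3L, minObsFrac = 0.7) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) stop("x must have promoter_id row names")
  if (length(times) != ncol(x)) stop("times must match ncol(x)")
  n <- ncol(x)
  if (stats::sd(times) == 0) stop("all sample times identical")
  tstd <- (times - mean(times)) / stats::sd(times)
  X <- outer(tstd, 0:degree, `^`)
  iFirst <- which.min(times)
  iLast <- which.max(times)

  betaNames <- paste0("beta", 0:degree)
  out <- data.frame(promoter_id = rownames(x),
                    n_obs = as.integer(rowSums(!is.na(x))),
                    stringsAsFactors = FALSE)
  for (b in betaNames) out[[b]] <- NA_real_
  out$r_squared <- NA_real_
  out$p_value <- NA_real_
  out$fitted_first <- NA_real_
  out$fitted_last <- NA_real_
  out$skipped <- NA_character_

  minObs <- ceiling(minObsFrac * n)
  fill <- function(i, beta, fitted, y) {
    yb <- mean(y)
    rss <- sum((y - fitted)^2)
    tss <- sum((y - yb)^2)
    r2 <- if (tss > 0) max(0, 1 - rss / tss) else 0
    df2 <- length(y) - degree - 1L
    p <- if (tss == 0) 1 else if (rss <= tss * 1e-15) 0 else {
      f <- ((tss - rss) / degree) / (rss / df2)
      stats::pf(f, degree, df2, lower.tail = FALSE)
    }
    list(beta = beta, r2 = r2, p = p)
  }

  complete <- which(rowSums(is.na(x)) == 0L)
  if (n - degree - 1L < 1L) {
    stop("not enough samples for a degree-", degree, " fit")
  }
  if (length(complete)) {
    if (length(unique(times)) < degree + 1L) {
      out$skipped[complete] <- "fewer distinct times than degree + 1"
    } else {
      Y <- t(x[complete, , drop = FALSE])
      qrX <- qr(X)
      B <- qr.coef(qrX, Y)
      B[is.na(B)] <- 0
      fit <- X %*% B
      res <- Y - fit
      rss <- colSums(res^2)
      ybar <- colMeans(Y)
      tss <- colSums((Y - rep(ybar, each = n))^2)
      r2 <- ifelse(tss > 0, pmax(0, 1 - rss / tss), 0)
      df2 <- n - degree - 1L
      f <- ((tss - rss) / degree) / (rss / df2)
      p <- stats::pf(f, degree, df2, lower.tail = FALSE)
      p[tss == 0] <- 1
      p[tss > 0 & rss <= tss * 1e-15] <- 0
      out[complete, betaNames] <- t(B)
      out$r_squared[complete] <- r2
      out$p_value[complete] <- p
      out$fitted_first[complete] <- fit[iFirst, ]
      out$fitted_last[complete] <- fit[iLast, ]
    }
  }

  partial <- setdiff(seq_len(nrow(x)), complete)
  for (i in partial) {
    obs <- which(!is.na(x[i, ]))
    if (length(obs) < minObs) {
      out$skipped[i] <- "fewer than minObsFrac of samples observed"
      next
    }
    if (length(unique(times[obs])) < degree + 1L ||
        length(obs) - degree - 1L < 1L) {
      out$skipped[i] <- "fewer distinct times than degree + 1"
      next
    }
    y <- x[i, obs]
    ft <- stats::lm.fit(X[obs, , drop = FALSE], y)
    beta <- ft$coefficients
    beta[is.na(beta)] <- 0
    fitted <- X[obs, , drop = FALSE] %*% beta
    st <- fill(i, beta, fitted, y)
    out[i, betaNames] <- st$beta
    out$r_squared[i] <- st$r2
    out$p_value[i] <- st$p
    oFirst <- obs[which.min(times[obs])]
    oLast <- obs[which.max(times[obs])]
    out$fitted_first[i] <- sum(X[oFirst, ] * beta)
    out$fitted_last[i] <- sum(X[oLast, ] * beta)
  }
  rownames(out) <- NULL
  out
}

#' Call developmentally dynamic promoters (DDPs)
#'
#' Benjamini-Hochberg FDR correction over all fitted promoters of one
#' organ; a promoter is a DDP when its adjusted p-value is at most `alpha`
#' and its goodness of fit reaches `r2Min` (R-squared >= 0.3 by default).
#' The trend direction is `Flat` for non-DDPs, otherwise the sign of the
#' fitted activity change from the earliest to the latest time point.
#'
#' @param fits table from [fitPromoterTrends()].
#' @param alpha FDR level (default 0.05).
#' @param r2Min minimum R-squared (default 0.3).
#' @return `fits` with added `q_value`, `is_ddp` and `direction`
#'   (`Up`/`Down`/`Flat`) columns.
#' @export
callDdps <- function(fits, alpha = 0.05, r2Min = 0.3) {
  ok <- is.na(fits$skipped)
  fits$q_value <- NA_real_
  fits$q_value[ok] <- stats::p.adjust(fits$p_value[ok], method = "BH")
  fits$is_ddp <- ok & fits$q_value <= alpha & fits$r_squared >= r2Min
  fits$is_ddp[is.na(fits$is_ddp)] <- FALSE
  d <- fits$fitted_last - fits$fitted_first
  fits$direction <- "Flat"
  fits$direction[fits$is_ddp & d > 0] <- "Up"
  fits$direction[fits$is_ddp & d < 0] <- "Down"
  fits
}

#' Bootstrap confidence band for a group trajectory
#'
#' Resamples promoters with replacement `B` times and reports, per stage,
#' the mean activity of the group together with percentile bounds of the
#' resampled means (2.5 and 97.5 percentiles for the default 95% band).
#'
#' @param stageMat numeric matrix, promoters x stages (per-stage mean
#'   activity per promoter).
#' @param B number of bootstrap resamples (default 1000).
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @param conf band coverage (default 0.95).
#' @return data.frame `stage`, `mean`, `lower`, `upper`.
#' @export
bootstrapTrajectory <- function(stageMat, B = 1000L, seed = NULL,
                                conf = 0.95) {
  stageMat <- as.matrix(stageMat)
  if (!nrow(stageMat)) stop("empty promoter group")
  est <- colMeans(stageMat, na.rm = TRUE)
  np <- nrow(stageMat)
  qs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  bmeans <- withSeed(seed, {
    idx <- matrix(sample.int(np, np * B, replace = TRUE), nrow = B)
    t(apply(idx, 1L, function(ii) {
      colMeans(stageMat[ii, , drop = FALSE], na.rm = TRUE)
    }))
  })
  if (ncol(stageMat) == 1L) bmeans <- matrix(bmeans, ncol = 1L)
  band <- apply(bmeans, 2L, stats::quantile, probs = qs, na.rm = TRUE)
  data.frame(
    stage = colnames(stageMat) %||% as.character(seq_along(est)),
    mean = unname(est), lower = unname(band[1L, ]),
    upper = unname(band[2L, ]), stringsAsFactors = FALSE)
}

#' Compare activity of DDPs against flat promoters
#'
#' Summarizes each promoter's per-stage mean activity by its maximum, mean
#' and median across developmental stages, then compares the DDP and flat
#' (fitted, non-dynamic) groups with a two-sided Wilcoxon rank-sum test
#' for each summary statistic.
#'
#' @param x numeric matrix, promoters x samples (absolute activity of one
#'   organ).
#' @param calls table from [callDdps()] for the same organ.
#' @param stages character/factor of stage labels per sample (column).
#' @return data.frame with one row per metric (`max`, `mean`, `median`):
#'   group sizes, group medians, rank-sum statistic `W` and `p_value`.
#'   All-`NA` statistics with a warning when either group is empty.
#' @export
compareDdpVsFlat <- function(x, calls, stages) {
  x <- as.matrix(x)
  if (length(stages) != ncol(x)) stop("stages must match ncol(x)")
  stageMeans <- t(rowsum(t(x), group = stages, na.rm = TRUE) /
                    as.vector(table(stages)[sort(unique(as.character(stages)))]))
  stats3 <- cbind(
    max = apply(stageMeans, 1L, max, na.rm = TRUE),
    mean = rowMeans(stageMeans, na.rm = TRUE),
    median = apply(stageMeans, 1L, stats::median, na.rm = TRUE))
  fitted <- calls$promoter_id[is.na(calls$skipped)]
  ddp <- calls$promoter_id[calls$is_ddp]
  flat <- setdiff(fitted, ddp)
  ddp <- intersect(ddp, rownames(x))
  flat <- intersect(flat, rownames(x))
  out <- data.frame(metric = c("max", "mean", "median"),
                    n_ddp = length(ddp), n_flat = length(flat),
                    median_ddp = NA_real_, median_flat = NA_real_,
                    W = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  if (!length(ddp) || !length(flat)) {
    warning("empty DDP or flat group; comparison not computed")
    return(out)
  }
  for (k in seq_len(3L)) {
    a <- stats3[ddp, k]
    b <- stats3[flat, k]
    wt <- stats::wilcox.test(a, b, alternative = "two.sided", exact = NULL)
    out$median_ddp[k] <- stats::median(a)
    out$median_flat[k] <- stats::median(b)
    out$W[k] <- unname(wt$statistic)
    out$p_value[k] <- wt$p.value
  }
  out
}
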