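#' Extract per-ROI mean Jacobian determinants
#'
#' Arithmetic mean of the Jacobian map over each atlas ROI. ROIs with no
#' labelled voxels yield NA with a warning.
#'
#' @param jacobian a \linkS4class{BrainVolume} of Jacobian determinants.
#' @param atlas a \linkS4class{LabelVolume} on the same grid.
#' @param subjectId,age bookkeeping columns for the output rows.
#' @return data.frame with columns subject_id, age, roi_name, mean_jacobian.
#' @export
extractRoiMeans <- function(jacobian, atlas, subjectId = "s", age = NA_real_) {
  if (!identical(dim(jacobian@data), dim(atlas@data))) stop("grids differ")
  L <- length(atlas@labelNames)
  means <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    sel <- atlas@data == l
    if (!any(sel)) {
      warning("empty ROI: ", atlas@labelNames[l])
      next
    }
    means[l] <- mean(jacobian@data[sel])
  }
  data.frame(subject_id = subjectId, age = age, roi_name = atlas@labelNames,
             mean_jacobian = means, stringsAsFactors = FALSE)
}

#' Linear and quadratic age regression per ROI
#'
#' Ordinary least squares of each ROI's mean Jacobian on age (linear model)
#' and on age + age^2 (quadratic model; age is centered at its sample mean
#' before squaring to decorrelate the terms, which leaves the age^2 t-test
#' unchanged). The reported p-value is the age-coefficient t-test for the
#' linear model and the age^2-coefficient t-test for the quadratic model.
#'
#' @param meas data.frame as returned by \code{\link{extractRoiMeans}},
#'   stacked over subjects.
#' @param q FDR level for \code{\link{bhFdr}} (applied separately within each
#'   model family across ROIs; default 0.05).
#' @return data.frame with one row per ROI x model: coefficients, adjusted
#'   R^2, p-value and FDR flag.
#' @export
fitAgeModels <- function(meas, q = 0.05) {
  meas <- meas[!is.na(meas$mean_jacobian), ]
  rois <- unique(meas$roi_name)
  rows <- list()
  for (roi in rois) {
    d <- meas[meas$roi_name == roi, ]
    if (nrow(d) < 4L) stop("need at least 4 subjects per ROI: ", roi)
    if (stats::var(d$age) == 0) stop("no age variance")
    lin <- stats::lm(mean_jacobian ~ age, data = d)
    slin <- summary(lin)
    aC <- d$age - mean(d$age)
    quad <- stats::lm(d$mean_jacobian ~ aC + I(aC^2))
    squad <- summary(quad)
    rows[[length(rows) + 1L]] <- data.frame(
      roi_name = roi, model = "linear",
      coef_age = stats::coef(lin)[["age"]], coef_age2 = NA_real_,
      adjusted_r2 = slin$adj.r.squared,
      r2 = slin$r.squared,
      p_value = slin$coefficients["age", "Pr(>|t|)"],
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      roi_name = roi, model = "quadratic",
      coef_age = stats::coef(quad)[["aC"]],
      coef_age2 = stats::coef(quad)[["I(aC^2)"]],
      adjusted_r2 = squad$adj.r.squared,
      r2 = squad$r.squared,
      p_value = squad$coefficients["I(aC^2)", "Pr(>|t|)"],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$fdr_significant <- FALSE
  for (m in unique(out$model)) {
    sel <- out$model == m
    out$fdr_significant[sel] <- bhFdr(out$p_value[sel], q)
  }
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR flags
#'
#' Step-up procedure at rate q: sort the p-values ascending, find the largest
#' rank i with p(i) <= i q / m and flag all ranks up to i. Implemented via
#' \code{stats::p.adjust(method = "BH") <= q}, which is equivalent.
#'
#' @param p numeric vector of p-values in [0,1].
#' @param q target false discovery rate (default 0.05).
#' @return logical vector of significance flags, in the input order.
#' @export
bhFdr <- function(p, q = 0.05) {
  if (length(p) == 0L) stop("empty p-value vector")
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH") <= q
}

#' One-way ANOVA with Scheffe post-hoc contrasts
#'
#' Classic one-way ANOVA F test across groups, followed by all pairwise
#' Scheffe comparisons: the pair statistic (mi - mj)^2 / (MSE (1/ni + 1/nj))
#' is referred to (k - 1) F(k - 1, N - k), making the procedure valid for
#' any contrast and conservative for pairs.
#'
#' @param groups named list of numeric vectors (>= 2 groups, >= 2 values
#'   each).
#' @param alpha significance level for the pairwise flags (default 0.05).
#' @return list with \code{F}, \code{p}, \code{df}, and a data.frame
#'   \code{pairs} (group1, group2, diff, p, significant).
#' @export
anovaScheffe <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups")
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L)) stop("every group needs at least 2 values")
  N <- sum(n)
  m <- vapply(groups, mean, numeric(1))
  grand <- sum(n * m) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw == 0 && ssb == 0) stop("degenerate: zero variance everywhere")
  dfb <- k - 1L
  dfw <- N - k
  mse <- ssw / dfw
  Fstat <- if (mse == 0) Inf else (ssb / dfb) / mse
  p <- stats::pf(Fstat, dfb, dfw, lower.tail = FALSE)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_len(k))
  pairs <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    diff <- m[i] - m[j]
    stat <- if (mse == 0) Inf else diff^2 / (mse * (1 / n[i] + 1 / n[j]))
    pij <- stats::pf(stat / dfb, dfb, dfw, lower.tail = FALSE)
    pairs[[length(pairs) + 1L]] <- data.frame(
      group1 = nm[i], group2 = nm[j], diff = diff, p = pij,
      significant = pij < alpha, stringsAsFactors = FALSE)
  }
  list(F = Fstat, p = p, df = c(dfb, dfw), pairs = do.call(rbind, pairs))
}
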