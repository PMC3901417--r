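#' @include AllClasses.R
NULL

.designFromColnames <- function(m) {
  parts <- strsplit(colnames(m), "_")
  data.frame(sample = colnames(m),
             stage = vapply(parts, `[`, "", 1),
             replicate = as.integer(vapply(parts, `[`, "", 2)),
             stringsAsFactors = FALSE)
}

#' Normalize an expression matrix
#'
#' Default: log2 transform followed by per-sample median centering (each
#' sample's median becomes 0). Zeros are offset by a configured
#' pseudo-intensity before the log. A passthrough mode leaves values
#' untouched.
#'
#' @param m probe x sample matrix of intensities
#' @param method "log2_median_center" or "passthrough"
#' @param pseudo pseudo-intensity added where values are 0
#' @return normalized matrix (attributes preserved)
#' @export
normalizeMatrix <- function(m, method = c("log2_median_center",
                                          "passthrough"), pseudo = 1) {
  method <- match.arg(method)
  if (any(!is.finite(m))) stop("non-finite intensities")
  if (method == "passthrough") return(m)
  if (any(m < 0)) stop("negative intensities cannot be log-transformed")
  x <- m
  x[x == 0] <- pseudo
  x <- log2(x)
  centered <- sweep(x, 2, apply(x, 2, median))
  attributes(centered)[c("design", "family")] <-
    attributes(m)[c("design", "family")]
  centered
}

#' One-way ANOVA with Fisher's LSD across stages
#'
#' Per probe: F = MS_between / MS_within on (k-1, N-k) degrees of freedom;
#' a probe is differentially expressed when p < alpha. For DE probes, the
#' three adjacent-stage contrasts (I-II, II-III, III-IV) are tested with
#' Fisher's LSD: two-sided t tests on the pooled within-stage variance
#' with N-k degrees of freedom at the same alpha. Probes with zero
#' within-stage variance are flagged degenerate (p = 0 when the means
#' differ, not DE when every value is identical). No multiple-testing
#' correction is applied by default, matching raw per-probe calls; set
#' \code{adjust = "BH"} for Benjamini-Hochberg on the ANOVA p-values.
#'
#' @param m probe x sample matrix; column names \code{<stage>_<replicate>}
#'   unless a design is attached as an attribute
#' @param alpha significance level
#' @param adjust "none" (default) or "BH"
#' @return data.frame: probe, F, p, de, one LSD flag column per adjacent
#'   stage pair, degenerate, family
#' @export
anovaLsd <- function(m, alpha = 0.01, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  design <- attr(m, "design")
  if (is.null(design)) design <- .designFromColnames(m)
  stages <- unique(design$stage)
  k <- length(stages)
  N <- ncol(m)
  if (k < 2) stop("need >= 2 stages")
  ns <- table(factor(design$stage, levels = stages))
  if (any(ns < 2)) stop("need >= 2 replicates in every stage")
  groupIdx <- lapply(stages, function(s) which(design$stage == s))
  means <- vapply(groupIdx, function(ix) rowMeans(m[, ix, drop = FALSE]),
                  numeric(nrow(m)))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  grand <- rowMeans(m)
  ssb <- as.vector(means^2 %*% as.numeric(ns)) - N * grand^2
  sst <- rowSums(m^2) - N * grand^2
  ssw <- pmax(sst - ssb, 0)
  dfb <- k - 1
  dfw <- N - k
  msb <- ssb / dfb
  msw <- ssw / dfw
  degenerate <- msw < 1e-12
  Fv <- ifelse(degenerate, NA_real_, msb / msw)
  p <- ifelse(degenerate, ifelse(ssb > 1e-12, 0, 1),
              pf(Fv, dfb, dfw, lower.tail = FALSE))
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  de <- p < alpha
  res <- data.frame(probe = rownames(m), F = Fv, p = p, de = de,
                    stringsAsFactors = FALSE)
  tcrit <- qt(1 - alpha / 2, dfw)
  for (j in seq_len(k - 1)) {
    sediff <- sqrt(msw * (1 / ns[j] + 1 / ns[j + 1]))
    tstat <- abs(means[, j] - means[, j + 1]) / sediff
    flag <- de & !degenerate & tstat > tcrit
    flag[degenerate] <- de[degenerate] &
      abs(means[degenerate, j] - means[degenerate, j + 1]) > 1e-12
    res[[paste0("lsd_", stages[j], "_", stages[j + 1])]] <- flag
  }
  res$degenerate <- degenerate
  fam <- attr(m, "family")
  res$family <- if (!is.null(fam)) unname(fam[res$probe]) else NA_character_
  rownames(res) <- NULL
  res
}

#' Roll probe-level DE calls up to miRNA families
#'
#' A family is differentially expressed when any member probe is; the
#' alternative mean-of-members rule collapses member probes to their mean
#' profile before testing and is available via
#' \code{\link{anovaLsd}} on a pre-averaged matrix.
#'
#' @param results data.frame from \code{\link{anovaLsd}}
#' @param familyMap optional named vector probe -> family (defaults to the
#'   family column of \code{results})
#' @return data.frame: family, members (comma-joined DE probes),
#'   n_members, min_p
#' @export
deFamilies <- function(results, familyMap = NULL) {
  fam <- if (!is.null(familyMap)) unname(familyMap[results$probe]) else
    results$family
  de <- results$de & !is.na(fam)
  if (!any(de))
    return(data.frame(family = character(), members = character(),
                      n_members = integer(), min_p = numeric(),
                      stringsAsFactors = FALSE))
  sel <- results[de, ]
  sel$fam <- fam[de]
  rows <- lapply(split(seq_len(nrow(sel)), sel$fam), function(ix) {
    data.frame(family = sel$fam[ix[1]],
               members = paste(sel$probe[ix], collapse = ","),
               n_members = length(ix), min_p = min(sel$p[ix]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$family), ]
}
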