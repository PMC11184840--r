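# Life-trait association battery: Kruskal-Wallis tests of each genome
# characteristic against trait and taxonomic-rank groupings, stratified
# ("blocked") by clade, with Benjamini-Hochberg FDR across the battery,
# epsilon-squared effect sizes and Dunn post-hoc comparisons.

#' Kruskal-Wallis rank test with explicit eligibility rules
#'
#' Wraps \code{stats::kruskal.test} (tie-corrected H, chi-square p on k-1
#' df) after dropping missing values and groups with fewer than
#' \code{minGroupSize} members. The fully degenerate case (all values
#' identical, H = 0) is reported as p = 1.
#'
#' @param values numeric vector.
#' @param groups group labels aligned with \code{values}.
#' @param minGroupSize minimum members per retained group (default 2).
#' @return list: H, df, p, n, k, group_ns (named), dropped_groups, or a
#'   skip record (\code{skipped = TRUE} with a reason) when fewer than two
#'   eligible groups remain.
#' @export
kruskalWallis <- function(values, groups, minGroupSize = 2L) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  sizes <- table(groups)
  small <- names(sizes)[sizes < minGroupSize]
  keep2 <- !groups %in% small
  values <- values[keep2]; groups <- groups[keep2]
  sizes <- table(groups)
  if (length(sizes) < 2L) {
    return(list(skipped = TRUE,
                reason = sprintf(
                  "fewer than 2 eligible groups (%d after dropping %d small)",
                  length(sizes), length(small)),
                dropped_groups = small, n = length(values),
                k = length(sizes)))
  }
  if (length(unique(values)) == 1L) {
    return(list(skipped = FALSE, H = 0, df = length(sizes) - 1L, p = 1,
                n = length(values), k = length(sizes),
                group_ns = c(sizes), dropped_groups = small))
  }
  kt <- stats::kruskal.test(values, factor(groups))
  list(skipped = FALSE, H = unname(kt$statistic),
       df = unname(kt$parameter), p = kt$p.value,
       n = length(values), k = length(sizes), group_ns = c(sizes),
       dropped_groups = small)
}

#' Epsilon-squared effect size for a Kruskal-Wallis test
#'
#' \code{H / (n - 1)}, the rank-based "variance explained", clipped to
#' \code{[0, 1]}.
#'
#' @param H Kruskal-Wallis statistic.
#' @param n total observations in the test.
#' @return effect size in \code{[0, 1]}.
#' @export
epsilonSquared <- function(H, n) {
  if (n < 2L) stop("epsilon-squared needs n >= 2")
  min(max(H / (n - 1), 0), 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values via \code{stats::p.adjust(method = "BH")},
#' with input validation.
#'
#' @param p numeric vector of p values in \code{[0, 1]} (NA passed through).
#' @return adjusted p values, capped at 1.
#' @export
bhFdr <- function(p) {
  ok <- is.na(p) | (p >= 0 & p <= 1)
  if (!all(ok)) stop("p values outside [0, 1]: ",
                     paste(utils::head(p[!ok]), collapse = ", "))
  stats::p.adjust(p, method = "BH")
}

#' Dunn post-hoc pairwise comparisons after Kruskal-Wallis
#'
#' Pairwise z statistics on joint ranks,
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)}}
#' with tie term \eqn{T = \sum (t^3 - t) / (12 (N - 1))}; two-sided normal p
#' values, BH-adjusted across the pairs.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param minGroupSize minimum members per retained group.
#' @return data.frame: group_i, group_j, z, p_raw, p_adj.
#' @export
dunnPosthoc <- function(values, groups, minGroupSize = 2L) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  sizes <- table(groups)
  keep2 <- groups %in% names(sizes)[sizes >= minGroupSize]
  values <- values[keep2]; groups <- groups[keep2]
  gl <- sort(unique(groups))
  if (length(gl) < 2L) stop("Dunn test needs >= 2 eligible groups")
  N <- length(values)
  r <- rank(values)
  tieCounts <- table(r)
  T <- sum(tieCounts^3 - tieCounts) / (12 * (N - 1))
  meanRank <- tapply(r, groups, mean)
  n <- table(groups)
  pairs <- utils::combn(gl, 2L)
  z <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - T) * (1 / n[[i1]] + 1 / n[[i2]]))
    z[j] <- (meanRank[[i1]] - meanRank[[i2]]) / se
  }
  pRaw <- 2 * stats::pnorm(-abs(z))
  data.frame(group_i = pairs[1, ], group_j = pairs[2, ], z = z,
             p_raw = pRaw, p_adj = bhFdr(pRaw), stringsAsFactors = FALSE)
}

#' Clade-blocked Kruskal-Wallis battery for one metric
#'
#' Runs the test of \code{metric} against \code{grouping} separately within
#' each level of \code{block} (stratified testing, matching per-clade
#' reporting) plus an unblocked "all" stratum, records skipped strata with
#' their reason (e.g. a clade whose members all share one trait level), and
#' BH-adjusts the p values within this battery.
#'
#' @param data data.frame keyed by species with metric, grouping and block
#'   columns.
#' @param metric name of the numeric metric column.
#' @param grouping name of the trait/rank column used as groups.
#' @param block name of the column defining strata (use NULL for only the
#'   pooled test).
#' @param minGroupSize minimum members per group within a stratum.
#' @return data.frame, one row per stratum: metric, grouping, block_var,
#'   block, n, k, H, df, p_raw, p_adj, epsilon_sq, group_ns, skipped,
#'   skip_reason. FDR is applied across the non-skipped rows of this call.
#' @export
blockedTests <- function(data, metric, grouping, block = NULL,
                         minGroupSize = 2L) {
  strata <- list(all = rep(TRUE, nrow(data)))
  if (!is.null(block)) {
    for (lev in sort(unique(stats::na.omit(data[[block]])))) {
      strata[[lev]] <- !is.na(data[[block]]) & data[[block]] == lev
    }
  }
  rows <- lapply(names(strata), function(lev) {
    sub <- data[strata[[lev]], , drop = FALSE]
    kw <- kruskalWallis(sub[[metric]], sub[[grouping]], minGroupSize)
    if (isTRUE(kw$skipped)) {
      data.frame(metric = metric, grouping = grouping,
                 block_var = block %||% "none", block = lev,
                 n = kw$n, k = kw$k, H = NA_real_, df = NA_integer_,
                 p_raw = NA_real_, p_adj = NA_real_,
                 epsilon_sq = NA_real_, group_ns = "",
                 skipped = TRUE, skip_reason = kw$reason,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(metric = metric, grouping = grouping,
                 block_var = block %||% "none", block = lev,
                 n = kw$n, k = kw$k, H = kw$H, df = kw$df,
                 p_raw = kw$p, p_adj = NA_real_,
                 epsilon_sq = epsilonSquared(kw$H, kw$n),
                 group_ns = paste(names(kw$group_ns), kw$group_ns,
                                  sep = "=", collapse = ";"),
                 skipped = FALSE, skip_reason = "",
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, rows)
  idx <- !res$skipped
  res$p_adj[idx] <- bhFdr(res$p_raw[idx])
  res
}

#' Full trait-association battery over metrics and groupings
#'
#' Convenience driver: every metric x grouping combination through
#' \code{\link{blockedTests}}, with the FDR family defined as one metric
#' across all groupings and blocks of this battery run (recorded in the
#' output).
#'
#' @param data merged species-level data.frame (composition + rates +
#'   labels).
#' @param metrics character vector of metric column names.
#' @param groupings character vector of grouping column names.
#' @param block stratifying column name (e.g. clade) or NULL.
#' @param minGroupSize minimum group size.
#' @return data.frame of stacked \code{\link{blockedTests}} results with an
#'   \code{fdr_family} column.
#' @export
traitBattery <- function(data, metrics, groupings, block = NULL,
                         minGroupSize = 2L) {
  out <- list()
  for (m in metrics) {
    rows <- do.call(rbind, lapply(groupings, function(g)
      blockedTests(data, m, g, block, minGroupSize)))
    # FDR family: one metric x all groupings x all blocks of this run
    idx <- !rows$skipped
    rows$p_adj[idx] <- bhFdr(rows$p_raw[idx])
    rows$fdr_family <- paste0("metric:", m)
    out[[m]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
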