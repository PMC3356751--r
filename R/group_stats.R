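#' Descriptive summary of one group of measurements
#'
#' @param values numeric vector, length >= 1.
#' @return One-row data frame: n, mean, median, sd, se, min, max. The
#'   sd (n - 1 denominator) and se = sd / sqrt(n) are `NA` for n = 1.
#' @export
describe_values <- function(values) {
  if (length(values) == 0L) stop("describe_values: empty input")
  if (anyNA(values)) stop("describe_values: NA values")
  n <- length(values)
  s <- if (n > 1L) stats::sd(values) else NA_real_
  data.frame(n = n, mean = mean(values), median = stats::median(values),
             sd = s, se = s / sqrt(n), min = min(values),
             max = max(values))
}

#' Omnibus test across groups
#'
#' Computes both the one-way ANOVA F test and the (tie-corrected)
#' Kruskal-Wallis H test across k groups. Downstream post-hoc testing
#' is gated on the test named by `gate`; the default gate is
#' Kruskal-Wallis, the rank-based companion of Dunn's test.
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @param gate `"kruskal"` (default) or `"anova"`.
#' @return List: `F`, `p_anova`, `H`, `p_kruskal`, `gate`, `p_gate`,
#'   `degenerate` (TRUE when all values are identical, in which case
#'   all p-values are reported as 1).
#' @export
omnibus_test <- function(groups, gate = c("kruskal", "anova")) {
  gate <- match.arg(gate)
  if (!is.list(groups) || length(groups) < 2L)
    stop("omnibus_test: need a list of >= 2 groups")
  if (any(vapply(groups, length, 0L) < 2L))
    stop("omnibus_test: every group needs n >= 2")
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  if (length(unique(x)) == 1L) {
    out <- list(F = 0, p_anova = 1, H = 0, p_kruskal = 1,
                gate = gate, p_gate = 1, degenerate = TRUE)
    return(out)
  }
  aovfit <- stats::oneway.test(x ~ g, var.equal = TRUE)
  kw <- stats::kruskal.test(x, g)
  p_gate <- if (gate == "kruskal") kw$p.value else aovfit$p.value
  list(F = unname(aovfit$statistic), p_anova = aovfit$p.value,
       H = unname(kw$statistic), p_kruskal = kw$p.value,
       gate = gate, p_gate = p_gate, degenerate = FALSE)
}

#' Dunn's rank-based post-hoc comparisons
#'
#' All observations are ranked jointly with mid-ranks for ties. For
#' groups i, j with mean ranks Rbar and sizes n, the statistic is
#' z_ij = (Rbar_i - Rbar_j) / sqrt((N (N + 1) / 12 -
#' sum(t^3 - t) / (12 (N - 1))) * (1 / n_i + 1 / n_j)), where the sum
#' runs over tie groups of size t. Two-sided p-values come from the
#' standard normal; groups of unequal (including zero) size are
#' handled — empty groups are dropped with a message. Pairs are
#' declared different when the (optionally multiplicity-adjusted)
#' p-value is <= alpha, and a compact letter display is emitted.
#'
#' @param groups named list of >= 2 numeric vectors (names default to
#'   group1, group2, ...).
#' @param alpha significance level in (0, 1), default 0.05.
#' @param adjust `"none"` (default; the omnibus gate is the only
#'   familywise control, as is traditional with Dunn-after-Kruskal),
#'   `"bonferroni"` or `"holm"`.
#' @return List: `comparisons` (data frame: group_i, group_j, z, p,
#'   p_adj, significant), `letters` (named character vector; groups
#'   sharing a letter are not significantly different), `mean_ranks`,
#'   `alpha`, `adjust`, `dropped` (names of empty groups excluded).
#' @export
dunn_posthoc <- function(groups, alpha = 0.05,
                         adjust = c("none", "bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  if (!is.list(groups) || length(groups) < 2L)
    stop("dunn_posthoc: need a list of >= 2 groups")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  empty <- vapply(groups, length, 0L) == 0L
  dropped <- names(groups)[empty]
  if (any(empty)) {
    message("dunn_posthoc: dropping empty group(s): ",
            paste(dropped, collapse = ", "))
    groups <- groups[!empty]
  }
  k <- length(groups)
  if (k < 2L) stop("dunn_posthoc: fewer than 2 non-empty groups")
  x <- unlist(groups)
  gi <- rep(seq_len(k), vapply(groups, length, 0L))
  N <- length(x)
  rk <- rank(x)  # mid-ranks for ties
  rbar <- tapply(rk, gi, mean)
  ns <- tabulate(gi, nbins = k)
  ties <- table(x)
  tiesum <- sum(ties^3 - ties)
  varterm <- N * (N + 1) / 12 - tiesum / (12 * (N - 1))
  pairs <- utils::combn(k, 2)
  z <- p <- numeric(ncol(pairs))
  for (m in seq_len(ncol(pairs))) {
    i <- pairs[1, m]; j <- pairs[2, m]
    se <- sqrt(varterm * (1 / ns[i] + 1 / ns[j]))
    z[m] <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    p[m] <- 2 * stats::pnorm(-abs(z[m]))
  }
  p_adj <- stats::p.adjust(p, method = adjust)
  sig <- p_adj <= alpha
  comp <- data.frame(group_i = names(groups)[pairs[1, ]],
                     group_j = names(groups)[pairs[2, ]],
                     z = z, p = p, p_adj = p_adj, significant = sig,
                     stringsAsFactors = FALSE)
  diff_mat <- matrix(FALSE, k, k,
                     dimnames = list(names(groups), names(groups)))
  for (m in seq_len(ncol(pairs)))
    diff_mat[pairs[1, m], pairs[2, m]] <-
      diff_mat[pairs[2, m], pairs[1, m]] <- sig[m]
  letters_out <- compact_letters(diff_mat)
  list(comparisons = comp, letters = letters_out,
       mean_ranks = stats::setNames(as.numeric(rbar), names(groups)),
       alpha = alpha, adjust = adjust, dropped = dropped)
}

#' Compact letter display from a pairwise difference matrix
#'
#' Insert-and-absorb algorithm: groups sharing at least one letter are
#' not significantly different; significantly different groups never
#' share a letter.
#'
#' @param diff_mat symmetric logical matrix; `TRUE` marks a significant
#'   difference. Dimnames give the group names.
#' @return Named character vector of letter strings.
#' @export
compact_letters <- function(diff_mat) {
  stopifnot(is.matrix(diff_mat), nrow(diff_mat) == ncol(diff_mat))
  k <- nrow(diff_mat)
  nm <- rownames(diff_mat)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!diff_mat[i, j]) next
    newcols <- list()
    for (col in cols) {
      if (col[i] && col[j]) {
        c1 <- col; c1[i] <- FALSE
        c2 <- col; c2[j] <- FALSE
        newcols <- c(newcols, list(c1, c2))
      } else {
        newcols <- c(newcols, list(col))
      }
    }
    # absorb columns contained in another
    keep <- rep(TRUE, length(newcols))
    for (a in seq_along(newcols)) for (b in seq_along(newcols)) {
      if (a != b && keep[a] && keep[b] &&
          all(newcols[[a]] <= newcols[[b]]) &&
          !identical(newcols[[a]], newcols[[b]]))
        keep[a] <- FALSE
    }
    # drop exact duplicates
    cols <- unique(newcols[keep])
  }
  # stable ordering: by first member index
  ord <- order(vapply(cols, function(col) which(col)[1], 0L))
  cols <- cols[ord]
  out <- vapply(seq_len(k), function(g) {
    paste0(letters[which(vapply(cols, function(col) col[g], TRUE))],
           collapse = "")
  }, "")
  stats::setNames(out, nm)
}

#' Table-1-style grouped summary with significance letters
#'
#' For each descriptor, groups records within each level of
#' `within` (default: within each stage, comparing panicle intervals),
#' computes descriptive statistics, runs the omnibus gate and — when it
#' is significant at `alpha` — Dunn's post-hoc test, attaching compact
#' significance letters. When the gate is not significant all groups
#' share the letter "a".
#'
#' @param df data frame of per-grain records including `stage` and
#'   `interval` columns plus the descriptor columns.
#' @param descriptors character vector of descriptor column names.
#' @param within `"stage"` (compare intervals within each stage;
#'   default) or `"interval"` (compare stages within each interval).
#' @param alpha significance level (default 0.05).
#' @param gate omnibus gate, see [omnibus_test()].
#' @param adjust multiplicity adjustment, see [dunn_posthoc()].
#' @return Data frame with one row per (within-level, group, descriptor):
#'   descriptive columns of [describe_values()] plus `letters`,
#'   `gate_p` and the settings used.
#' @export
group_table <- function(df, descriptors, within = c("stage", "interval"),
                        alpha = 0.05, gate = c("kruskal", "anova"),
                        adjust = c("none", "bonferroni", "holm")) {
  within <- match.arg(within)
  gate <- match.arg(gate)
  adjust <- match.arg(adjust)
  stopifnot(all(c("stage", "interval") %in% names(df)),
            all(descriptors %in% names(df)))
  byvar <- within
  grpvar <- setdiff(c("stage", "interval"), within)
  out <- list()
  for (lev in unique(df[[byvar]])) {
    sub <- df[df[[byvar]] == lev, , drop = FALSE]
    glev <- sort(unique(sub[[grpvar]]))
    for (d in descriptors) {
      gl <- lapply(glev, function(g) {
        v <- sub[[d]][sub[[grpvar]] == g]
        v[!is.na(v)]  # grains without a defined value drop out
      })
      names(gl) <- as.character(glev)
      gl <- gl[vapply(gl, length, 0L) > 0L]
      if (length(gl) == 0L) next
      usable <- vapply(gl, length, 0L) >= 2L
      if (length(gl) >= 2L && all(usable)) {
        om <- omnibus_test(gl, gate = gate)
        if (!om$degenerate && om$p_gate <= alpha) {
          dn <- dunn_posthoc(gl, alpha = alpha, adjust = adjust)
          lets <- dn$letters
        } else {
          lets <- stats::setNames(rep("a", length(gl)), names(gl))
        }
        gate_p <- om$p_gate
      } else {
        lets <- stats::setNames(rep("a", length(gl)), names(gl))
        gate_p <- NA_real_
      }
      for (g in names(gl)) {
        desc <- describe_values(gl[[g]])
        row <- cbind(data.frame(byvar = lev, group = g, descriptor = d,
                                stringsAsFactors = FALSE),
                     desc,
                     data.frame(letters = unname(lets[g]), gate_p = gate_p,
                                gate = gate, alpha = alpha, adjust = adjust,
                                stringsAsFactors = FALSE))
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  names(res)[names(res) == "byvar"] <- within
  names(res)[names(res) == "group"] <- grpvar
  rownames(res) <- NULL
  res
}
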