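#' One-way fixed-effects analysis of variance
#'
#' Standard one-way decomposition computed directly from sums of squares:
#' between-group SS on k - 1 degrees of freedom, within-group (error) SS on
#' N - k, F their mean-square ratio, p from the F distribution. Implemented
#' explicitly (rather than via a model-fitting wrapper) because the error
#' mean square and its degrees of freedom feed straight into Duncan's range
#' procedure.
#'
#' Degenerate inputs follow the usual conventions: if every observation is
#' identical the decomposition is 0/0 and F is reported as 0 with p = 1; if
#' the within-group variance is zero but means differ, F is infinite and
#' p = 0.
#'
#' @param data A data frame in long form.
#' @param value,group Column names (unquoted) holding the response and the
#'   grouping factor.
#' @return An object of class `anova_oneway`: group summaries, sums of
#'   squares, `mse`, `df_error`, `f_stat`, `p_value`. Use [tidy()] /
#'   [glance()] for tibble views.
#' @export
#' @examples
#' df <- data.frame(g = rep(c("a", "b", "c"), each = 5),
#'                  y = c(rnorm(5, 10), rnorm(5, 12), rnorm(5, 14)))
#' fit <- anova_oneway(df, y, g)
#' glance(fit)
anova_oneway <- function(data, value, group) {
  value <- rlang::ensym(value)
  group <- rlang::ensym(group)
  df <- tibble::tibble(
    group = as.character(dplyr::pull(data, !!group)),
    value = as.numeric(dplyr::pull(data, !!value))
  )
  if (any(!is.finite(df$value))) {
    stop("non-finite observations", call. = FALSE)
  }
  groups <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     ss = sum((.data$value - mean(.data$value))^2),
                     .groups = "drop")
  if (nrow(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(groups$n < 2)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(groups$group[groups$n < 2], collapse = ", "), call. = FALSE)
  }
  big_n <- sum(groups$n)
  grand <- sum(groups$n * groups$mean) / big_n
  ss_between <- sum(groups$n * (groups$mean - grand)^2)
  ss_within <- sum(groups$ss)
  df_between <- nrow(groups) - 1L
  df_error <- big_n - nrow(groups)
  mse <- ss_within / df_error
  msb <- ss_between / df_between
  if (mse > 0) {
    f_stat <- msb / mse
    p_value <- stats::pf(f_stat, df_between, df_error, lower.tail = FALSE)
  } else if (ss_between > 0) {
    f_stat <- Inf
    p_value <- 0
  } else {
    f_stat <- 0
    p_value <- 1
  }
  groups <- groups |>
    dplyr::mutate(se = sqrt(mse / .data$n)) |>
    dplyr::select("group", "n", "mean", "se")
  structure(
    list(groups = groups, ss_between = ss_between, ss_within = ss_within,
         df_between = df_between, df_error = df_error,
         mse = mse, f_stat = f_stat, p_value = p_value),
    class = "anova_oneway"
  )
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat("One-way ANOVA: ", nrow(x$groups), " groups, df = (",
      x$df_between, ", ", x$df_error, ")\n",
      "  F = ", format(x$f_stat, digits = 4),
      ", p = ", format.pval(x$p_value, digits = 4),
      ", MSE = ", format(x$mse, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname anova_oneway
#' @param x An `anova_oneway` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.anova_oneway <- function(x, ...) x$groups

#' @rdname anova_oneway
#' @exportS3Method generics::glance
glance.anova_oneway <- function(x, ...) {
  tibble::tibble(n_groups = nrow(x$groups), df_between = x$df_between,
                 df_error = x$df_error, mse = x$mse,
                 statistic = x$f_stat, p.value = x$p_value)
}

#' Duncan's multiple range test
#'
#' Stepwise post-hoc comparison of group means using span-dependent
#' critical values from the studentized range distribution. For a range
#' covering p ordered means the protection level is `(1 - alpha)^(p - 1)`,
#' i.e. the critical value is
#' `r_p = qtukey((1 - alpha)^(p - 1), p, df_error)` and the least
#' significant range is `LSR_p = r_p * sqrt(MSE / n)`, with the harmonic
#' mean of the group sizes standing in for n when the design is
#' unbalanced. Means are sorted in descending order (ties broken by label);
#' a range of means is declared non-significant if its end-point difference
#' is at most its LSR *or* if it is contained in a wider range already
#' found non-significant (the classical protection rule, which keeps the
#' resulting grouping consistent). Homogeneous subgroups are then encoded
#' as a compact letter display: two groups share a letter exactly when the
#' procedure does not separate them.
#'
#' @param anova An [anova_oneway()] fit.
#' @param alpha Significance level in (0, 0.5\]; default 0.05.
#' @return An object of class `duncan_mrt` with elements `groups` (tibble:
#'   `group`, `n`, `mean`, `se`, `letters`, sorted by descending mean),
#'   `lsr` (tibble: `span`, `critical`, `lsr`), `separated` (logical
#'   matrix over groups), `alpha`, `n_harmonic` and the `anova` fit.
#' @export
#' @examples
#' df <- data.frame(g = rep(letters[1:4], each = 6),
#'                  y = rep(c(10, 10.4, 12, 14), each = 6) + rnorm(24, 0, 0.8))
#' duncan_mrt(anova_oneway(df, y, g))
duncan_mrt <- function(anova, alpha = 0.05) {
  stopifnot(inherits(anova, "anova_oneway"))
  if (!is.finite(alpha) || alpha <= 0 || alpha > 0.5) {
    stop("`alpha` must lie in (0, 0.5]", call. = FALSE)
  }
  if (anova$df_error < 1) stop("error degrees of freedom < 1", call. = FALSE)
  groups <- dplyr::arrange(anova$groups, dplyr::desc(.data$mean), .data$group)
  k <- nrow(groups)
  n_h <- k / sum(1 / groups$n)
  spans <- seq_len(k)[-1]
  critical <- stats::qtukey((1 - alpha)^(spans - 1), spans, anova$df_error)
  lsr <- critical * sqrt(anova$mse / n_h)
  sep <- duncan_separation(groups$mean, lsr, spans)
  dimnames(sep) <- list(groups$group, groups$group)
  letter_sets <- assign_letters(sep, groups$group)
  groups$letters <- unname(letter_sets[groups$group])
  structure(
    list(anova = anova, alpha = alpha, n_harmonic = n_h,
         lsr = tibble::tibble(span = spans, critical = critical, lsr = lsr),
         groups = groups, separated = sep),
    class = "duncan_mrt"
  )
}

# Range scan with containment protection. Means must be sorted descending;
# lsr[i] is the least significant range for spans[i]. Returns a symmetric
# logical matrix: TRUE where the procedure separates a pair.
duncan_separation <- function(means, lsr, spans) {
  k <- length(means)
  sep <- matrix(FALSE, k, k)
  nonsig <- matrix(FALSE, k, k)  # marks ranges covered by a non-significant one
  for (span in rev(spans)) {
    threshold <- lsr[match(span, spans)]
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      significant <- !nonsig[i, j] && (means[i] - means[j] > threshold)
      if (significant) {
        sep[i, j] <- sep[j, i] <- TRUE
      } else {
        for (a in i:j) for (b in a:j) nonsig[a, b] <- TRUE
      }
    }
  }
  sep
}

#' Compact letter display from a separation relation
#'
#' Assigns letters to groups ordered by descending mean such that two
#' groups share at least one letter exactly when the separation relation
#' does not distinguish them. Each maximal run of consecutive groups that
#' are mutually non-separated receives one letter; runs contained in a
#' longer run are absorbed. The relation must be symmetric, irreflexive
#' and interval-structured along the given order (as range procedures with
#' containment protection always produce).
#'
#' @param separated Symmetric logical matrix; `TRUE` where a pair is
#'   significantly separated. Rows/columns follow `order`.
#' @param order Group labels in descending-mean order.
#' @return Named character vector of letter strings, in `order`.
#' @export
#' @examples
#' sep <- matrix(FALSE, 3, 3); sep[1, 3] <- sep[3, 1] <- TRUE
#' assign_letters(sep, c("A", "B", "C"))   # "a"  "ab" "b"
assign_letters <- function(separated, order) {
  k <- length(order)
  if (!is.matrix(separated) || !identical(dim(separated), c(k, k))) {
    stop("`separated` must be a ", k, " x ", k, " matrix", call. = FALSE)
  }
  if (!isSymmetric(unname(separated))) {
    stop("separation relation must be symmetric", call. = FALSE)
  }
  if (any(diag(separated))) {
    stop("separation relation must be irreflexive", call. = FALSE)
  }
  # maximal intervals of mutually non-separated consecutive groups
  intervals <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(separated[i:j, j + 1])) j <- j + 1
    intervals[[i]] <- c(i, j)
  }
  keep <- !vapply(seq_len(k), function(i) {
    any(vapply(seq_len(k)[-i], function(m) {
      intervals[[m]][1] <= intervals[[i]][1] &&
        intervals[[m]][2] >= intervals[[i]][2]
    }, TRUE))
  }, TRUE)
  intervals <- intervals[keep]
  symbols <- c(letters, as.vector(outer(letters, letters, paste0)))
  out <- stats::setNames(rep("", k), order)
  for (idx in seq_along(intervals)) {
    span <- intervals[[idx]]
    members <- span[1]:span[2]
    out[members] <- paste0(out[members], symbols[idx])
  }
  out
}

#' @export
print.duncan_mrt <- function(x, ...) {
  cat("Duncan's multiple range test (alpha = ", x$alpha, ")\n", sep = "")
  print.data.frame(as.data.frame(x$groups), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @rdname duncan_mrt
#' @param x A `duncan_mrt` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.duncan_mrt <- function(x, ...) x$groups

#' @rdname duncan_mrt
#' @exportS3Method generics::glance
glance.duncan_mrt <- function(x, ...) {
  dplyr::mutate(glance(x$anova), alpha = x$alpha, n_harmonic = x$n_harmonic)
}

#' One-call ANOVA + Duncan lettering
#'
#' Convenience wrapper: fit [anova_oneway()] and run [duncan_mrt()].
#'
#' @inheritParams anova_oneway
#' @inheritParams duncan_mrt
#' @return A `duncan_mrt` object.
#' @export
duncan_letters <- function(data, value, group, alpha = 0.05) {
  value <- rlang::ensym(value)
  group <- rlang::ensym(group)
  duncan_mrt(anova_oneway(data, !!value, !!group), alpha = alpha)
}

#' Duncan letters for every trait x stage x condition cell
#'
#' Runs one ANOVA + Duncan comparison of the cultivars per trait, stage and
#' watering condition — the machine twin of the letter annotations on
#' phenotyping bar charts, where letters compare cultivars within one
#' treatment.
#'
#' @param traits A plant-level trait table as from [simulate_traits()]:
#'   columns `cultivar`, `stage`, `condition`, plus the four trait columns.
#' @param alpha Significance level (default 0.05).
#' @param trait_cols Trait columns to analyse.
#' @return A tibble: `trait`, `stage`, `condition`, `cultivar`, `n`,
#'   `mean`, `se`, `letters`, sorted by descending mean within each cell.
#' @export
#' @examples
#' traits <- simulate_traits(example_panel(n = 4, seed = 1))
#' compare_cultivars(traits)
compare_cultivars <- function(traits, alpha = 0.05,
                              trait_cols = c("taproot_length", "shoot_length",
                                             "root_dm", "shoot_dm")) {
  long <- traits |>
    tidyr::pivot_longer(dplyr::all_of(trait_cols),
                        names_to = "trait", values_to = "value")
  long |>
    dplyr::group_by(.data$trait, .data$stage, .data$condition) |>
    dplyr::group_modify(function(df, key) {
      fit <- duncan_letters(df, value, cultivar, alpha = alpha)
      dplyr::rename(fit$groups, cultivar = "group")
    }) |>
    dplyr::ungroup()
}
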