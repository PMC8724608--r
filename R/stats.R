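# Differential abundance and ordination.
#
# Per-analyte Welch t-tests stand in for a feature-level mixed model:
# glycoform contrasts are tested on relative-abundance fractions (the
# scale on which the profiles are reported), protein contrasts on log2
# normalized intensities with a stringent default alpha of 1e-5.

.welch_contrast <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    return(list(p = NA_real_, n_a = length(a), n_b = length(b)))
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    return(list(p = p, n_a = length(a), n_b = length(b)))
  }
  list(p = stats::t.test(b, a)$p.value, n_a = length(a), n_b = length(b))
}

#' Differential glycoform abundance between two conditions
#'
#' Per glycoform, a two-sided Welch t-test compares relative-abundance
#' fractions between the replicates of two conditions; the effect size
#' is `log2(mean_B / mean_A)`. Swapping the conditions negates the
#' log2 fold change and leaves the p-value unchanged. Raw p-values
#' decide significance (`p < alpha`); a Benjamini–Hochberg column is
#' emitted for information only.
#'
#' @param profiles Glycoform profile tibble from [glycoform_fractions()].
#' @param design Tibble mapping `sample` to `condition`.
#' @param condition_a,condition_b The two condition labels (B vs A).
#' @param alpha Significance threshold on the raw p-value (default
#'   0.05).
#' @param on_log If `TRUE`, test log-transformed fractions (zeros
#'   dropped) instead of raw fractions.
#' @return A `glyco_contrast` tibble: `family`, `glycoform`, `log2fc`,
#'   `p`, `p_adj`, `n_a`, `n_b`, `significant`.
#' @export
glycoform_contrast <- function(profiles, design, condition_a, condition_b,
                               alpha = 0.05, on_log = FALSE) {
  .contrast_table(
    profiles |> dplyr::mutate(value = .data$fraction),
    id_cols = c("family", "glycoform"),
    design, condition_a, condition_b, alpha,
    transform = if (on_log) function(x) log(x[x > 0]) else identity,
    fc_from = "mean"
  )
}

#' Differential protein abundance between two conditions
#'
#' Per protein, a two-sided Welch t-test on log2 intensities
#' (zero intensities are dropped from the test and from the means, with
#' a note in the result). The default threshold keeps the stringent
#' alpha of 1e-5 customary for protein-level DIA contrasts.
#'
#' @param proteins Protein-level abundance tibble (normalized), columns
#'   `protein`, `sample`, `intensity`.
#' @param design Tibble mapping `sample` to `condition`.
#' @param condition_a,condition_b The two condition labels (B vs A).
#' @param alpha Significance threshold on the raw p-value (default
#'   1e-5).
#' @return A `glyco_contrast` tibble: `protein`, `log2fc`, `p`, `p_adj`,
#'   `n_a`, `n_b`, `significant`.
#' @export
protein_contrast <- function(proteins, design, condition_a, condition_b,
                             alpha = 1e-5) {
  .contrast_table(
    proteins |> dplyr::mutate(value = .data$intensity),
    id_cols = "protein",
    design, condition_a, condition_b, alpha,
    transform = function(x) log2(x[x > 0]),
    fc_from = "log2"
  )
}

.contrast_table <- function(tbl, id_cols, design, condition_a, condition_b,
                            alpha, transform, fc_from) {
  stopifnot(all(c("sample", "condition") %in% names(design)))
  tbl <- tbl |> dplyr::inner_join(design, by = "sample") |>
    dplyr::filter(.data$condition %in% c(condition_a, condition_b))
  res <- tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(id_cols))) |>
    dplyr::summarise(
      .res = {
        raw_a <- .data$value[.data$condition == condition_a]
        raw_b <- .data$value[.data$condition == condition_b]
        w <- .welch_contrast(transform(raw_a), transform(raw_b))
        log2fc <- if (fc_from == "log2") {
          mean(log2(raw_b[raw_b > 0])) - mean(log2(raw_a[raw_a > 0]))
        } else {
          log2(mean(raw_b, na.rm = TRUE) / mean(raw_a, na.rm = TRUE))
        }
        list(tibble::tibble(log2fc = log2fc, p = w$p,
                            n_a = w$n_a, n_b = w$n_b))
      },
      .groups = "drop"
    ) |>
    tidyr::unnest(".res") |>
    dplyr::mutate(
      p_adj = stats::p.adjust(.data$p, method = "BH"),
      significant = !is.na(.data$p) & .data$p < alpha
    )
  class(res) <- c("glyco_contrast", class(res))
  attr(res, "alpha") <- alpha
  attr(res, "conditions") <- c(A = condition_a, B = condition_b)
  res
}

#' Principal component analysis of sample profiles
#'
#' Pivots a long abundance (or fraction) tibble to a samples-by-analytes
#' matrix, optionally log-transforms, drops analytes with missing
#' values (counted and recorded), centers, and runs [stats::prcomp()].
#'
#' @param tbl Long tibble with a `sample` column, one or more id
#'   columns, and a value column.
#' @param value Name of the value column (default `"intensity"`, use
#'   `"fraction"` for glycoform profiles).
#' @param n_components Number of components to retain (default 2; must
#'   not exceed the number of samples).
#' @param log_transform If `TRUE`, analyze `log2(value + offset)` where
#'   zeros make `offset` the smallest positive value; fractions are
#'   usually analyzed untransformed.
#' @return A `glyco_pca` object: list with `scores` (tibble `sample`,
#'   `PC1`, `PC2`, ...), `explained` (variance fractions, descending),
#'   `n_dropped` (analytes removed for missingness) and the underlying
#'   `prcomp` fit. Degenerate input (zero total variance) yields zero
#'   scores with a warning.
#' @export
pca_scores <- function(tbl, value = "intensity", n_components = 2,
                       log_transform = FALSE) {
  stopifnot("sample" %in% names(tbl))
  id_cols <- setdiff(names(tbl), c("sample", value))
  wide <- tbl |>
    tidyr::unite(".analyte", dplyr::all_of(id_cols)) |>
    tidyr::pivot_wider(names_from = ".analyte",
                       values_from = dplyr::all_of(value))
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$sample
  if (nrow(m) < n_components) {
    stop("fewer samples (", nrow(m), ") than components requested",
         call. = FALSE)
  }
  keep <- colSums(is.na(m)) == 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " analyte(s) with missing values dropped")
  }
  m <- m[, keep, drop = FALSE]
  if (log_transform) {
    pos <- m[m > 0]
    offset <- if (any(m == 0)) min(pos) else 0
    m <- log2(m + offset)
  }
  centered <- scale(m, center = TRUE, scale = FALSE)
  total_var <- sum(centered^2)
  if (total_var < .Machine$double.eps * length(centered)) {
    warning("samples are identical: PCA is degenerate, scores set to 0",
            call. = FALSE)
    scores <- matrix(0, nrow(m), n_components)
    explained <- rep(0, n_components)
  } else {
    fit <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    k <- min(n_components, ncol(fit$x))
    scores <- fit$x[, seq_len(k), drop = FALSE]
    explained <- (fit$sdev^2 / sum(fit$sdev^2))[seq_len(k)]
  }
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  out <- list(
    scores = tibble::tibble(sample = rownames(m),
                            tibble::as_tibble(scores)),
    explained = explained,
    n_dropped = n_dropped,
    fit = if (exists("fit", inherits = FALSE)) fit else NULL
  )
  class(out) <- "glyco_pca"
  out
}

#' @export
print.glyco_pca <- function(x, ...) {
  cat("PCA of", nrow(x$scores), "samples;",
      "explained variance:",
      paste0(sprintf("%.1f%%", 100 * x$explained), collapse = ", "), "\n")
  print(x$scores)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy glyco_pca
#' @export
tidy.glyco_pca <- function(x, ...) {
  x$scores |>
    tidyr::pivot_longer(-"sample", names_to = "component",
                        values_to = "score")
}

#' @method glance glyco_pca
#' @export
glance.glyco_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_components = length(x$explained),
    var_explained = sum(x$explained),
    n_dropped = x$n_dropped
  )
}

#' @method tidy glyco_contrast
#' @export
tidy.glyco_contrast <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "glyco_contrast")
  out
}

#' @method glance glyco_contrast
#' @export
glance.glyco_contrast <- function(x, ...) {
  tibble::tibble(
    n_tested = sum(!is.na(x$p)),
    n_significant = sum(x$significant, na.rm = TRUE),
    alpha = attr(x, "alpha")
  )
}
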