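# Gene-level significance and the distributional summaries used to judge
# identification quality: combined p-values, BH q-values, count histograms,
# delta-mass normal quantiles, and the goodness-of-fit test against the
# random-assignment null model.

#' Combined (cumulative) p-value
#'
#' Combines per-peptide p-values into one gene-level value. The `"product"`
#' method is the plain product of the p-values (the "cumulative p-value");
#' `"fisher"` converts `-2 * sum(log p)` to a p-value on a chi-square
#' distribution with `2k` degrees of freedom, which is the statistically
#' calibrated alternative.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param method `"product"` (default) or `"fisher"`.
#' @return A single combined value.
#' @examples
#' cumulative_p(c(0.1, 0.1))             # 0.01
#' cumulative_p(c(0.1, 0.2, 0.3), "fisher")
#' @export
cumulative_p <- function(p_values, method = c("product", "fisher")) {
  method <- match.arg(method)
  if (length(p_values) == 0) stop("empty p-value list")
  if (any(p_values <= 0))
    stop("p-value of 0 (or below) signals upstream underflow")
  if (any(p_values > 1)) stop("p-values must be <= 1")
  if (method == "product") prod(p_values)
  else stats::pchisq(-2 * sum(log(p_values)), df = 2 * length(p_values),
                     lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted q-values; the output preserves the input order.
#' Zeros are tolerated (they arise when a product cumulative p-value
#' underflows double precision) and map to q = 0.
#'
#' @param values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(values) {
  if (length(values) == 0) return(numeric(0))
  if (any(is.na(values)) || any(values < 0) || any(values > 1))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(values, method = "BH")
}

#' Count genes passing an FDR threshold
#'
#' @param summaries Gene summaries with a `q_value` column.
#' @param level FDR level (e.g. 0.01).
#' @return Integer count of gene symbols with `q_value <= level`.
#' @export
genes_at_fdr <- function(summaries, level) {
  sum(summaries$q_value <= level)
}

#' Count distribution (histogram)
#'
#' @param x Bin values (e.g. peptides per gene symbol, or log10-intensity
#'   bin left edges).
#' @param freq Non-negative frequencies, one per bin.
#' @return A `count_distribution` data.frame sorted by `x`.
#' @export
count_distribution <- function(x, freq) {
  if (length(x) != length(freq)) stop("x and freq must have equal length")
  if (any(freq < 0)) stop("frequencies must be >= 0")
  if (anyDuplicated(x)) stop("bin values must be unique")
  ord <- order(x)
  structure(data.frame(x = x[ord], freq = as.numeric(freq[ord])),
            class = c("count_distribution", "data.frame"))
}

#' Tabulate raw values into a count distribution
#'
#' @param values Numeric vector of observed values.
#' @return A `count_distribution` over the distinct values.
#' @export
as_count_distribution <- function(values) {
  tab <- table(values)
  count_distribution(as.numeric(names(tab)), as.numeric(tab))
}

#' Peptide counts per gene symbol
#'
#' @param summaries Gene summaries (see [gene_rollup()]).
#' @return A `count_distribution` over `peptide_count`.
#' @export
peptide_count_distribution <- function(summaries) {
  if (nrow(summaries) == 0)
    return(count_distribution(numeric(0), numeric(0)))
  as_count_distribution(summaries$peptide_count)
}

#' Log10 intensity histograms per treatment
#'
#' Bins `log10(intensity)` at a fixed width (left-closed bins identified by
#' their left edge), separately for each treatment group. Records with
#' non-positive intensity are excluded with a warning.
#'
#' @param psms PSM data.frame with `intensity` and `treatment`.
#' @param binwidth Bin width on the log10 scale (default 0.25).
#' @return Named list of `count_distribution` objects, one per treatment.
#' @export
intensity_histogram <- function(psms, binwidth = 0.25) {
  bad <- psms$intensity <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-positive intensity excluded")
    psms <- psms[!bad, , drop = FALSE]
  }
  groups <- split(psms$intensity, psms$treatment)
  lapply(groups, function(int) {
    bins <- floor(log10(int) / binwidth) * binwidth
    as_count_distribution(bins)
  })
}

#' Delta-mass normal quantiles
#'
#' Computes observed-minus-theoretical precursor masses and pairs their
#' order statistics with standard normal quantiles for a Q-Q plot, plus
#' summary statistics (mean, sd, fraction inside +/- 2 Da).
#'
#' @param psms PSM data.frame (uses `precursor_mz`, `charge`, `peptide`,
#'   `mod_mass`).
#' @param table A [residue_mass_table()].
#' @return A list of class `delta_mass_qq`: `delta` (sorted), `quantiles`
#'   (matching normal quantiles), `mean`, `sd`, `fraction_within_2da`,
#'   `degenerate` (TRUE when sd is 0).
#' @export
delta_mass_quantiles <- function(psms, table = residue_mass_table()) {
  mod <- if ("mod_mass" %in% names(psms)) psms$mod_mass else 0
  theo <- peptide_mass(psms$peptide, mod_mass = mod, table = table)
  d <- delta_mass(psms$precursor_mz, psms$charge, theo, table = table)
  d <- sort(d)
  n <- length(d)
  s <- if (n > 1) stats::sd(d) else 0
  structure(
    list(delta = d,
         quantiles = stats::qnorm(stats::ppoints(n)),
         mean = mean(d),
         sd = s,
         fraction_within_2da = if (n > 0) sum(abs(d) <= 2) / n else NA_real_,
         degenerate = n > 1 && s < 1e-12),
    class = "delta_mass_qq"
  )
}

#' @export
print.delta_mass_qq <- function(x, ...) {
  cat(sprintf(
    "Delta mass: n=%d, mean=%.4f Da, sd=%.4f Da, %.1f%% within +/-2 Da%s\n",
    length(x$delta), x$mean, x$sd, 100 * x$fraction_within_2da,
    if (isTRUE(x$degenerate)) " [degenerate: zero spread]" else ""))
  invisible(x)
}

#' Goodness of fit of an observed count distribution against a null
#'
#' Pearson chi-square test of an observed histogram against a null
#' histogram. The null is rescaled to the observed total, and bins with
#' expected counts below `pool_threshold` are pooled into the tail before
#' computing the statistic. Used to compare the peptides-per-protein
#' distribution of real identifications against random-spectra expectation.
#'
#' @param observed,null `count_distribution` objects (or named numeric
#'   vectors mapping bin value to frequency).
#' @param pool_threshold Minimum expected count per bin (default 5).
#' @return An object of class `htest` with the chi-square `statistic`,
#'   degrees of freedom (`parameter`), `p.value`, and a `direction` note
#'   stating which distribution has the heavier right tail.
#' @export
goodness_of_fit <- function(observed, null, pool_threshold = 5) {
  obs <- .as_hist(observed)
  nul <- .as_hist(null)
  if (sum(nul$freq) == 0) stop("null distribution has zero total")
  if (sum(obs$freq) == 0) stop("observed distribution has zero total")
  xs <- sort(union(obs$x, nul$x))
  o <- setNames(numeric(length(xs)), xs)
  e <- o
  o[as.character(obs$x)] <- obs$freq
  e[as.character(nul$x)] <- nul$freq
  e <- e / sum(e) * sum(o)
  # pool under-populated bins into the right tail
  while (length(e) > 1 && any(e < pool_threshold)) {
    i <- max(which(e < pool_threshold))
    j <- if (i == length(e)) i - 1L else length(e)
    e[j] <- e[j] + e[i]
    o[j] <- o[j] + o[i]
    e <- e[-i]
    o <- o[-i]
  }
  stat <- sum((o - e)^2 / e)
  df <- length(e) - 1L
  p <- if (df >= 1) stats::pchisq(stat, df = df, lower.tail = FALSE) else 1
  mean_obs <- sum(obs$x * obs$freq) / sum(obs$freq)
  mean_nul <- sum(nul$x * nul$freq) / sum(nul$freq)
  direction <- if (mean_obs > mean_nul)
    "observed right-shifted vs null (excess of multi-peptide proteins)"
  else if (mean_obs < mean_nul) "observed left-shifted vs null"
  else "no mean shift"
  structure(
    list(statistic = c("X-squared" = stat),
         parameter = c(df = df),
         p.value = p,
         method = "Pearson goodness-of-fit against scaled null (tail-pooled)",
         data.name = "observed vs null count distribution",
         direction = direction),
    class = "htest"
  )
}

.as_hist <- function(h) {
  if (inherits(h, "count_distribution")) return(h)
  if (is.numeric(h) && !is.null(names(h)))
    return(count_distribution(as.numeric(names(h)), as.numeric(h)))
  stop("expected a count_distribution or named numeric vector")
}

#' Gene-level summaries from a peptide p-value table
#'
#' Recomputes the gene-symbol-level significance inventory from a table of
#' per-peptide p-values (e.g. a published peptide-level supplement):
#' cumulative p-value per gene symbol, BH q-values across gene symbols, and
#' the distinct-peptide-observation (RANK1) count.
#'
#' @param peptide_pvalues data.frame with columns `gene_symbol`, `peptide`,
#'   `p_value` (one row per RANK1 peptide observation). Rows with empty gene
#'   symbols are excluded from the gene rollup.
#' @param method Combination method passed to the gene rollup.
#' @return List with `summaries` (gene_symbol, peptide_count,
#'   log10_cumulative_p, cumulative_p, q_value), `n_rank1` (total peptide
#'   observations), and `n_no_symbol`.
#' @export
summarize_peptide_pvalues <- function(peptide_pvalues,
                                      method = c("product", "fisher")) {
  method <- match.arg(method)
  need <- c("gene_symbol", "peptide", "p_value")
  missing_cols <- setdiff(need, names(peptide_pvalues))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  n_rank1 <- nrow(peptide_pvalues)
  keep <- peptide_pvalues$gene_symbol != ""
  dt <- data.table::as.data.table(peptide_pvalues[keep, , drop = FALSE])
  if (nrow(dt) == 0) {
    summ <- data.frame(gene_symbol = character(0),
                       peptide_count = integer(0),
                       log10_cumulative_p = numeric(0),
                       cumulative_p = numeric(0), q_value = numeric(0))
    return(list(summaries = summ, n_rank1 = n_rank1,
                n_no_symbol = sum(!keep)))
  }
  summ <- dt[, .(peptide_count = .N,
                 peptide_p_values = list(sort(p_value))),
             by = gene_symbol]
  data.table::setorder(summ, gene_symbol)
  summ <- data.table::setDF(summ)
  if (method == "product") {
    log10p <- vapply(summ$peptide_p_values, function(p) sum(log10(p)),
                     numeric(1))
    summ$log10_cumulative_p <- log10p
    summ$cumulative_p <- 10^log10p
  } else {
    summ$cumulative_p <- vapply(summ$peptide_p_values,
                                function(p) cumulative_p(p, "fisher"),
                                numeric(1))
    summ$log10_cumulative_p <- log10(summ$cumulative_p)
  }
  summ$q_value <- bh_fdr(summ$cumulative_p)
  summ$peptide_p_values <- NULL
  list(summaries = summ, n_rank1 = n_rank1, n_no_symbol = sum(!keep))
}
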