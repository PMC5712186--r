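# Generic category-distribution enrichment over a user-supplied annotation:
# the computation a network/annotation service performs when it asks whether
# a gene set is a random assemblage. The null of random expectation is the
# hypergeometric distribution; corrections are Bonferroni and
# Benjamini-Hochberg.

#' Build an annotation table
#'
#' @param terms data.frame with columns `term_id`, `description`, `gene`
#'   (long format, one gene per row; see [read_annotation_table()]).
#' @param background Character vector: the background gene universe. Every
#'   annotated gene must belong to it.
#' @return An `annotation_table`: list with `terms` (list of gene sets named
#'   by term), `descriptions`, `background`.
#' @export
annotation_table <- function(terms, background) {
  need <- c("term_id", "description", "gene")
  missing_cols <- setdiff(need, names(terms))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  background <- unique(background)
  outside <- setdiff(unique(terms$gene), background)
  if (length(outside) > 0)
    stop("annotated gene(s) not in background: ",
         paste(utils::head(outside, 5), collapse = ", "),
         if (length(outside) > 5) ", ..." else "")
  sets <- lapply(split(terms$gene, terms$term_id), unique)
  if (any(lengths(sets) == 0)) stop("term gene sets must be non-empty")
  desc <- terms$description[match(names(sets), terms$term_id)]
  structure(list(terms = sets,
                 descriptions = setNames(desc, names(sets)),
                 background = background),
            class = "annotation_table")
}

#' Category enrichment of a gene set
#'
#' For each term, the upper-tail hypergeometric probability of observing at
#' least the seen number of annotated genes when drawing the gene set at
#' random from the background. Bonferroni multiplies by the number of terms
#' tested; BH q-values come from [bh_fdr()] over the same universe. By
#' default only terms overlapping the gene set count as tested hypotheses
#' (`universe = "nonzero"`); terms outside the universe get p = 1
#' corrections. This is a generic reimplementation of the category test --
#' external annotation services' exact internals are not reproduced.
#'
#' @param gene_set Character vector of gene symbols; genes outside the
#'   background are dropped with a warning.
#' @param annotation An [annotation_table()].
#' @param universe `"nonzero"` (default) or `"all"`: which terms count as
#'   tested hypotheses for the corrections.
#' @return data.frame sorted by ascending p-value: `term_id`, `description`,
#'   `count_in_set`, `term_size`, `p_value`, `p_fdr`, `p_bonferroni`.
#' @export
enrich <- function(gene_set, annotation,
                   universe = c("nonzero", "all")) {
  universe <- match.arg(universe)
  if (!inherits(annotation, "annotation_table"))
    stop("annotation must be an annotation_table")
  if (length(annotation$terms) == 0) stop("empty annotation")
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0) stop("empty gene set")
  dropped <- setdiff(gene_set, annotation$background)
  if (length(dropped) > 0) {
    warning(length(dropped), " gene(s) outside the background dropped")
    gene_set <- intersect(gene_set, annotation$background)
    if (length(gene_set) == 0) stop("empty gene set after background filter")
  }
  N <- length(annotation$background)
  n <- length(gene_set)
  K <- lengths(annotation$terms)
  k <- vapply(annotation$terms,
              function(g) length(intersect(g, gene_set)), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tested <- if (universe == "nonzero") k >= 1 else rep(TRUE, length(k))
  n_tested <- sum(tested)
  p_bonf <- rep(1, length(p))
  p_fdr <- rep(1, length(p))
  if (n_tested > 0) {
    p_bonf[tested] <- pmin(1, p[tested] * n_tested)
    p_fdr[tested] <- bh_fdr(p[tested])
  }
  out <- data.frame(
    term_id = names(annotation$terms),
    description = unname(annotation$descriptions),
    count_in_set = k,
    term_size = unname(K),
    p_value = unname(p),
    p_fdr = p_fdr,
    p_bonferroni = p_bonf,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
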