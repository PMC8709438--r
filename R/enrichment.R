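# COG functional-category enrichment of genes carrying a motif in their
# promoter: one-sided hypergeometric over-representation test with
# Benjamini-Hochberg FDR control across categories.

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least `k` marked genes when `n` genes are drawn without
#' replacement from a universe of `N` genes of which `K` are marked.
#' Vectorised over its arguments.
#'
#' @param k Observed marked draws.
#' @param n Number of draws (foreground size).
#' @param K Marked genes in the universe.
#' @param N Universe size.
#' @return Probability in `[0, 1]`.
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  if (any(k < 0) || any(k > n) || any(n > N) || any(K > N) || any(K < 0)) {
    stop("require 0 <= k <= n <= N and 0 <= K <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; the input order is
#' preserved. Idempotent on its own output.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' COG-category enrichment of a gene set
#'
#' Tests each COG category for over-representation among foreground
#' genes (typically: genes carrying a motif in their promoter) relative
#' to the background of all genes with at least one COG category. Genes
#' with several categories count once in each; p-values are upper-tail
#' hypergeometric, adjusted across tested categories by
#' Benjamini-Hochberg.
#'
#' @param foreground Character vector of foreground `gene_id`s, or a
#'   logical vector along `genes`.
#' @param genes A `gene_features` data frame (column `cog` holds the
#'   category letters of each gene).
#' @param alternative `"over"` (default; enrichment) or `"under"`
#'   (depletion, lower tail).
#' @return Data frame sorted by `p_value` with columns `category`, `k`
#'   (foreground genes in category), `n` (foreground size), `K`
#'   (background genes in category), `N` (background size), `p_value`,
#'   `p_adj`. The background universe (annotated genes only) is recorded
#'   in the `universe` attribute.
#' @export
cog_enrichment <- function(foreground, genes,
                           alternative = c("over", "under")) {
  alternative <- match.arg(alternative)
  if (is.logical(foreground)) {
    stopifnot(length(foreground) == nrow(genes))
    foreground <- genes$gene_id[foreground]
  }
  annotated <- genes[!is.na(genes$cog) & genes$cog != "", , drop = FALSE]
  N <- nrow(annotated)
  fg <- annotated[annotated$gene_id %in% foreground, , drop = FALSE]
  n <- nrow(fg)
  if (n == 0L) stop("empty foreground after restricting to annotated genes")
  cats_bg <- strsplit(annotated$cog, "", fixed = TRUE)
  cats_fg <- strsplit(fg$cog, "", fixed = TRUE)
  K_tab <- table(unlist(lapply(cats_bg, unique)))
  k_tab <- table(unlist(lapply(cats_fg, unique)))
  categories <- sort(names(K_tab))
  k <- as.integer(k_tab[categories])
  k[is.na(k)] <- 0L
  K <- as.integer(K_tab[categories])
  p <- if (alternative == "over") {
    hypergeom_upper_tail(k, n, K, N)
  } else {
    stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  }
  out <- data.frame(category = categories, k = k, n = n, K = K, N = N,
                    p_value = p, p_adj = bh_adjust(p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$category), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "universe") <- "genes with >= 1 COG category"
  out
}
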