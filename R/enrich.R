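# Over-representation engine on GMT gene-set libraries: hypergeometric
# upper-tail p, BH adjustment across tested terms, deviation-formula odds
# ratio against a fixed background, combined score OR * (-ln p), and
# regulation annotation of the overlap.

#' Gene-set library container
#'
#' @param terms named list of character vectors (term -> gene symbols);
#'   symbols are uppercased and deduplicated.
#' @param name library name.
#' @param background_size background gene count `N` (default 20000); must be
#'   at least the size of every term.
#' @return an object of class `gene_set_library`.
#' @export
gene_set_library <- function(terms, name = "library", background_size = 20000) {
  if (length(terms) == 0 || is.null(names(terms)))
    stop("terms must be a non-empty named list")
  terms <- lapply(terms, function(g) unique(toupper(g)))
  sizes <- vapply(terms, length, 0L)
  if (any(sizes == 0)) stop("term sets must be non-empty")
  if (background_size < max(sizes))
    stop("background_size must be >= the largest term")
  lib <- list(name = name, terms = terms,
              background_size = as.integer(background_size))
  class(lib) <- "gene_set_library"
  lib
}

#' Read / write a GMT gene-set library
#'
#' Standard GMT: tab-separated lines of term name, description, then member
#' genes. Lines with fewer than 3 fields are an error reporting the line
#' number.
#'
#' @param path GMT file path.
#' @param background_size background gene count attached to the library.
#' @return `read_gmt()` returns a [gene_set_library()].
#' @export
read_gmt <- function(path, background_size = 20000) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 0L) < 3)
  if (length(short) > 0)
    stop("GMT line ", short[1], " has fewer than 3 fields in ", path)
  terms <- lapply(fields, function(f) f[-(1:2)])
  names(terms) <- vapply(fields, `[[`, "", 1)
  gene_set_library(terms, name = basename(path),
                   background_size = background_size)
}

#' @rdname read_gmt
#' @param library a [gene_set_library()].
#' @export
write_gmt <- function(library, path) {
  stopifnot(inherits(library, "gene_set_library"))
  lines <- vapply(names(library$terms), function(tn)
    paste(c(tn, "na", library$terms[[tn]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

check_counts <- function(k, n, m, N) {
  if (any(k < 0) || any(k > pmin(n, m)) || any(n > N) || any(m > N))
    stop("need 0 <= k <= min(n, m) and n, m <= N")
}

#' Hypergeometric over-representation p-value
#'
#' Upper tail `P(X >= k)` for X hypergeometric with population `N`, `m`
#' successes, and `n` draws.
#'
#' @param k overlap size.
#' @param n query size.
#' @param m term size.
#' @param N background size.
#' @return probability (vectorized).
#' @export
hypergeom_p <- function(k, n, m, N) {
  check_counts(k, n, m, N)
  stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Deviation-formula odds ratio
#'
#' `OR = k * (N - m - n + k) / ((n - k) * (m - k))`; when the query or the
#' term is fully contained in the overlap (`n == k` or `m == k`) a 0.5
#' continuity correction is added to all four contingency cells.
#'
#' @inheritParams hypergeom_p
#' @return odds ratio (vectorized).
#' @export
enrichr_odds_ratio <- function(k, n, m, N) {
  check_counts(k, n, m, N)
  plain <- k * (N - m - n + k) / ((n - k) * (m - k))
  cc <- (k + 0.5) * (N - m - n + k + 0.5) / ((n - k + 0.5) * (m - k + 0.5))
  ifelse(n - k == 0 | m - k == 0, cc, plain)
}

#' Combined enrichment score
#'
#' `OR * (-ln p)`; 0 when p = 1.
#'
#' @param odds_ratio odds ratio.
#' @param p raw enrichment p-value in (0, 1].
#' @return combined score (vectorized).
#' @export
combined_score <- function(odds_ratio, p) {
  if (any(p <= 0) || any(p > 1)) stop("p must lie in (0, 1]")
  odds_ratio * (-log(p))
}

#' Over-representation analysis of a query gene set
#'
#' One row per library term overlapping the query (`k >= 1`): hypergeometric
#' p, BH adjustment across the tested (overlapping) terms, deviation-formula
#' odds ratio, combined score, overlap genes, and a regulation label (`up`
#' if every overlap gene is labeled up, `down` if all down, else `mixed`).
#' Query genes absent from the background are retained in the query size n.
#' Rows are sorted by p ascending.
#'
#' @param query_genes character vector of gene symbols.
#' @param library a [gene_set_library()].
#' @param regulation optional named vector (gene -> `"up"`/`"down"`).
#' @return data frame with columns `term`, `k`, `n`, `m`, `N`, `overlap`,
#'   `p`, `p_adj`, `odds_ratio`, `combined_score`, `genes`, `regulation`.
#' @export
enrich <- function(query_genes, library, regulation = NULL) {
  stopifnot(inherits(library, "gene_set_library"))
  query <- unique(toupper(query_genes))
  if (length(query) == 0) stop("query must be non-empty")
  if (!is.null(regulation)) names(regulation) <- toupper(names(regulation))
  n <- length(query)
  N <- library$background_size
  rows <- lapply(names(library$terms), function(tn) {
    hit <- intersect(query, library$terms[[tn]])
    k <- length(hit)
    if (k == 0) return(NULL)
    m <- length(library$terms[[tn]])
    reg <- "mixed"
    if (!is.null(regulation)) {
      labs <- unique(regulation[hit])
      labs <- labs[!is.na(labs)]
      if (length(labs) == 1) reg <- labs
    }
    data.frame(term = tn, k = k, n = n, m = m, N = N,
               overlap = paste0(k, "/", m),
               p = hypergeom_p(k, n, m, N),
               odds_ratio = enrichr_odds_ratio(k, n, m, N),
               genes = paste(hit, collapse = "; "),
               regulation = reg,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      m = integer(0), N = integer(0), overlap = character(0),
                      p = numeric(0), p_adj = numeric(0),
                      odds_ratio = numeric(0), combined_score = numeric(0),
                      genes = character(0), regulation = character(0)))
  rows$p_adj <- bh_adjust(rows$p)
  rows$combined_score <- combined_score(rows$odds_ratio, rows$p)
  rows <- rows[order(rows$p), c("term", "k", "n", "m", "N", "overlap", "p",
                                "p_adj", "odds_ratio", "combined_score",
                                "genes", "regulation")]
  rownames(rows) <- NULL
  rows
}
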