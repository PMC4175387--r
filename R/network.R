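#' Canonicalize gene identifiers
#'
#' KGML gene entries carry names like `"sce:YBR160W"`; input networks usually
#' use bare ORF names. Both are mapped onto a common form: any database/organism
#' prefix up to the last `":"` is stripped and the remainder is uppercased, so
#' `"sce:ybr160w"` and `"YBR160W"` denote the same gene.
#'
#' @param x Character vector of raw identifiers.
#' @return Character vector of canonical identifiers.
#' @export
#' @examples
#' canonical_gene_id(c("sce:YBR160W", "ybr160w"))
canonical_gene_id <- function(x) {
  stopifnot(is.character(x))
  toupper(sub("^.*:", "", trimws(x)))
}

# Canonical unordered edge matrix: two character columns, each row sorted,
# duplicate rows and self-loops removed, rows ordered lexicographically.
canonical_edges <- function(from, to) {
  if (length(from) != length(to)) stop("edge endpoint vectors differ in length")
  if (length(from) == 0L) {
    return(matrix(character(), ncol = 2L, dimnames = list(NULL, c("from", "to"))))
  }
  a <- pmin(from, to)
  b <- pmax(from, to)
  keep <- a != b
  a <- a[keep]
  b <- b[keep]
  m <- unique(cbind(from = a, to = b))
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' Construct an undirected gene network
#'
#' The container used both for converted pathway gold standards and for
#' inferred input networks: a set of gene identifiers plus a set of
#' unordered, simple edges (no self-loops, no duplicates). Genes without
#' any incident edge are retained.
#'
#' @param edges Two-column character matrix or data frame of edges, or `NULL`.
#' @param genes Character vector of gene identifiers; endpoints of `edges`
#'   are added automatically.
#' @param label Free-text provenance (pathway id or file name).
#' @return An object of class `gene_network` with elements `genes`
#'   (sorted character vector), `edges` (canonical two-column matrix) and
#'   `label`.
#' @export
#' @examples
#' gene_network(cbind(c("a", "b"), c("b", "c")), label = "toy")
gene_network <- function(edges = NULL, genes = character(), label = "") {
  if (is.null(edges)) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (!is.matrix(edges) || (ncol(edges) != 2L && nrow(edges) > 0L)) {
    stop("'edges' must be a two-column matrix or data frame")
  }
  storage.mode(edges) <- "character"
  em <- canonical_edges(edges[, 1L], if (ncol(edges) >= 2L) edges[, 2L] else character())
  structure(
    list(
      genes = sort(unique(c(as.character(genes), as.vector(em)))),
      edges = em,
      label = as.character(label)[1L]
    ),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf(
    "gene_network%s: %d genes, %d edges\n",
    if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
    length(x$genes), nrow(x$edges)
  ))
  invisible(x)
}

#' Number of edges in a gene network
#' @param net A `gene_network`.
#' @return Integer edge count.
#' @export
edge_count <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  nrow(net$edges)
}

# Keyed representation "a|b" used for set operations on edges.
edge_keys <- function(net) {
  if (nrow(net$edges) == 0L) return(character())
  paste(net$edges[, 1L], net$edges[, 2L], sep = "\r")
}

#' Convert a gene network to an igraph graph
#'
#' Isolated genes become isolated vertices.
#'
#' @param net A `gene_network`.
#' @return An undirected simple `igraph` graph whose vertex names are the
#'   gene identifiers.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  igraph::graph_from_data_frame(
    as.data.frame(net$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$genes, stringsAsFactors = FALSE)
  )
}

#' Test two gene networks for structural equality
#'
#' Equality on gene set and edge set; the `label` field is ignored.
#'
#' @param a,b `gene_network` objects.
#' @return Logical scalar.
#' @export
network_equal <- function(a, b) {
  identical(a$genes, b$genes) && identical(unname(a$edges), unname(b$edges))
}

#' Read a gene network from a SIF or TSV edge list
#'
#' SIF lines are whitespace-separated `source relation target [target ...]`;
#' TSV lines are `source<TAB>target`. In both formats a line with a single
#' token declares an isolated gene, lines starting with `#` are comments,
#' duplicate edges are collapsed and self-loops are dropped with a warning.
#'
#' @param path File to read.
#' @param format `"sif"` or `"tsv"`; default guesses from the file extension
#'   (`.sif` means SIF, anything else TSV).
#' @param canonicalize Apply [canonical_gene_id()] (default `TRUE`).
#' @return A `gene_network` labelled with the file name.
#' @export
read_network <- function(path, format = c("auto", "sif", "tsv"),
                         canonicalize = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  }
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  from <- character()
  to <- character()
  lone <- character()
  for (i in idx) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    tok <- tok[nzchar(tok)]
    if (length(tok) == 1L) {
      lone <- c(lone, tok)
    } else if (format == "sif") {
      if (length(tok) < 3L) {
        stop(sprintf("line %d of '%s' is not valid SIF: '%s'", i, path, lines[i]))
      }
      from <- c(from, rep(tok[1L], length(tok) - 2L))
      to <- c(to, tok[-(1:2)])
    } else {
      if (length(tok) != 2L) {
        stop(sprintf("line %d of '%s' is not a two-column edge: '%s'", i, path, lines[i]))
      }
      from <- c(from, tok[1L])
      to <- c(to, tok[2L])
    }
  }
  if (canonicalize) {
    from <- canonical_gene_id(from)
    to <- canonical_gene_id(to)
    lone <- canonical_gene_id(lone)
  }
  n_self <- sum(from == to)
  if (n_self > 0L) {
    warning(sprintf("dropped %d self-loop(s) while reading '%s'", n_self, path))
  }
  gene_network(cbind(from, to), genes = c(lone, from, to), label = basename(path))
}

#' Write a gene network to a SIF or TSV edge list
#'
#' The first line is a `#` comment header recording the label and the node
#' and edge counts; isolated genes are written as single-token lines so the
#' file round-trips through [read_network()] exactly.
#'
#' @param net A `gene_network`.
#' @param path Output file.
#' @param format `"sif"` (relation token `pp`) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("sif", "tsv")) {
  stopifnot(inherits(net, "gene_network"))
  format <- match.arg(format)
  header <- sprintf(
    "# gene network%s: %d nodes, %d edges",
    if (nzchar(net$label)) paste0(" '", net$label, "'") else "",
    length(net$genes), nrow(net$edges)
  )
  body <- if (nrow(net$edges) > 0L) {
    if (format == "sif") {
      paste(net$edges[, 1L], "pp", net$edges[, 2L], sep = "\t")
    } else {
      paste(net$edges[, 1L], net$edges[, 2L], sep = "\t")
    }
  } else {
    character()
  }
  isolated <- setdiff(net$genes, as.vector(net$edges))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(header, body, isolated), con)
  invisible(path)
}
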