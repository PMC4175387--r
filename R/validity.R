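#' Level of a gene pair in a gold-standard network
#'
#' The level of a relationship is the number of edges on the shortest
#' undirected path between the two genes in the gold-standard network. A
#' directly connected pair has level 1; a pair joined through one
#' intermediate gene has level 2.
#'
#' @param net The gold-standard `gene_network`.
#' @param a,b Character vectors of gene identifiers (recycled to a common
#'   length); `a[i] == b[i]` is an error.
#' @return Integer vector of levels; `NA` where either gene is absent from
#'   `net` or no path exists.
#' @export
#' @examples
#' gp <- gene_network(cbind(c("3", "3", "5"), c("2", "5", "7")))
#' gnv_level(gp, "3", "7") # 2
gnv_level <- function(net, a, b) {
  stopifnot(inherits(net, "gene_network"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  if (any(a == b)) stop("level is undefined for identical genes")
  out <- rep(NA_integer_, n)
  present <- a %in% net$genes & b %in% net$genes
  if (any(present)) {
    g <- as_igraph(net)
    va <- unique(a[present])
    vb <- unique(b[present])
    d <- igraph::distances(g, v = va, to = vb)
    lv <- d[cbind(match(a[present], va), match(b[present], vb))]
    lv[!is.finite(lv)] <- NA
    out[present] <- as.integer(lv)
  }
  out
}

#' Prune an input network against a pathway
#'
#' Restricts the input network to edges whose both endpoints are genes of
#' the pathway network; edges touching any gene absent from the pathway are
#' removed (no information exists to judge them), and genes left without an
#' incident edge are dropped.
#'
#' @param input_net Inferred `gene_network` to evaluate.
#' @param pathway_net Converted pathway `gene_network` (or any gold
#'   standard).
#' @return The pruned `gene_network`.
#' @export
prune_network <- function(input_net, pathway_net) {
  stopifnot(inherits(input_net, "gene_network"), inherits(pathway_net, "gene_network"))
  keep <- input_net$edges[, 1L] %in% pathway_net$genes &
    input_net$edges[, 2L] %in% pathway_net$genes
  gene_network(input_net$edges[keep, , drop = FALSE], label = input_net$label)
}

#' Score the validity of a gene network against a gold standard
#'
#' The level-weighted matching distance. After optional pruning, every edge
#' `(a, b)` of the input network is assigned the level
#' `l = ` [gnv_level()]`(pathway_net, a, b)`; edges with `1 <= l <= n`
#' increment the hit count at their level (each edge counts at exactly one
#' level), and all input edges count toward the evaluated edge total
#' `||E_I||`. The summary statistics are
#'
#' * cumulative hits `H_n = sum_{l=1..n} Hit_l / l`,
#' * cumulative failures `F_n = ||E_I|| - H_n`,
#' * validity `V_n = H_n / ||E_I||`, a proportion in `[0, 1]`.
#'
#' Input edges whose endpoints are absent from, or disconnected in, the
#' gold standard are failures at every level.
#'
#' @param input_net Inferred `gene_network`.
#' @param pathway_net Gold-standard `gene_network` (typically from
#'   [convert_pathway()]).
#' @param n Maximum level considered (`n >= 1`); level 2 is the recommended
#'   default.
#' @param do_prune Prune the input against the pathway's gene set first
#'   (default `TRUE`; use `FALSE` to score against a user-supplied whole
#'   gold standard).
#' @return A `validity_result` with fields `level_cap`, `hits_per_level`
#'   (`Hit_1..Hit_n`), `cumulative_hits`, `failures`, `validity`,
#'   `evaluated_edges` and `label`. When no edges remain after pruning the
#'   validity is undefined and reported as `NA`.
#' @export
#' @examples
#' gi <- gene_network(cbind(c("3", "3"), c("2", "7")))
#' gp <- gene_network(cbind(c("3", "3", "5"), c("2", "5", "7")))
#' gnv_score(gi, gp, n = 2)
gnv_score <- function(input_net, pathway_net, n = 2L, do_prune = TRUE) {
  stopifnot(inherits(input_net, "gene_network"), inherits(pathway_net, "gene_network"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be an integer >= 1")
  evaluated <- if (do_prune) prune_network(input_net, pathway_net) else input_net
  m <- nrow(evaluated$edges)
  hits <- stats::setNames(integer(n), paste0("hit_", seq_len(n)))
  if (m > 0L) {
    lv <- gnv_level(pathway_net, evaluated$edges[, 1L], evaluated$edges[, 2L])
    counted <- lv[!is.na(lv) & lv <= n]
    if (length(counted) > 0L) {
      tab <- table(factor(counted, levels = seq_len(n)))
      hits[] <- as.integer(tab)
    }
  }
  h <- sum(hits / seq_len(n))
  structure(
    list(
      level_cap = n,
      hits_per_level = hits,
      cumulative_hits = h,
      failures = m - h,
      validity = if (m > 0L) h / m else NA_real_,
      evaluated_edges = m,
      label = paste0(input_net$label, " vs ", pathway_net$label)
    ),
    class = "validity_result"
  )
}

#' @export
print.validity_result <- function(x, ...) {
  cat(sprintf("validity_result (%s), level cap n = %d\n", x$label, x$level_cap))
  cat("  ", paste(sprintf("%s = %d", names(x$hits_per_level), x$hits_per_level),
                  collapse = ", "), "\n", sep = "")
  cat(sprintf("  H_%d = %.4g, F_%d = %.4g, ||E_I|| = %d\n",
              x$level_cap, x$cumulative_hits, x$level_cap, x$failures,
              x$evaluated_edges))
  if (is.na(x$validity)) {
    cat("  V = undefined (no evaluable edges)\n")
  } else {
    cat(sprintf("  V_%d = %.4g\n", x$level_cap, x$validity))
  }
  invisible(x)
}

#' Flatten validity results to a data frame
#'
#' @param results A `validity_result` or list of them.
#' @return A data frame with one row per result: `label`, `hit_1..hit_n`,
#'   `cumulative_hits`, `failures`, `validity`, `evaluated_edges`.
#' @export
validity_table <- function(results) {
  if (inherits(results, "validity_result")) results <- list(results)
  n <- max(vapply(results, function(r) r$level_cap, integer(1)))
  rows <- lapply(results, function(r) {
    hits <- stats::setNames(rep(NA_integer_, n), paste0("hit_", seq_len(n)))
    hits[names(r$hits_per_level)] <- r$hits_per_level
    c(list(label = r$label), as.list(hits),
      list(cumulative_hits = r$cumulative_hits, failures = r$failures,
           validity = r$validity, evaluated_edges = r$evaluated_edges))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Classical precision of an input network against a pathway
#'
#' The baseline used before level-weighted matching: the gold standard is
#' the relation-only graph of the pathway (direct gene-gene relations, no
#' compound bridging), the input is pruned against that gold standard's
#' gene set, and precision is the fraction of remaining input edges present
#' in the gold standard.
#'
#' @param input_net Inferred `gene_network`.
#' @param pathway A [pathway()] object, or a `gene_network` already holding
#'   the relation-only gold standard.
#' @return Precision in `[0, 1]`, or `NA` when no input edge survives
#'   pruning.
#' @export
classical_precision <- function(input_net, pathway) {
  gold <- if (inherits(pathway, "gene_network")) pathway else relation_gold_standard(pathway)
  pruned <- prune_network(input_net, gold)
  m <- nrow(pruned$edges)
  if (m == 0L) return(NA_real_)
  sum(edge_keys(pruned) %in% edge_keys(gold)) / m
}
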