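# Worked-example networks used throughout: a two-edge input network and a
# three-edge gold-standard path in which genes 3 and 2 are adjacent and
# genes 3 and 7 lie two edges apart.
worked_example_input <- function() {
  gene_network(cbind(c("3", "3"), c("2", "7")), label = "worked-input")
}
worked_example_gold <- function() {
  gene_network(cbind(c("3", "3", "5"), c("2", "5", "7")), label = "worked-gold")
}

# Pathway mirroring the simplest conversion figure: genes 1-8 with direct
# relations, plus compound c1 bridging genes 3 and 8 and compound c2
# bridging genes 6 and 7.
fig2_pathway <- function() {
  entries <- c(
    lapply(1:8, function(i) pathway_entry(as.character(i), "gene",
                                          names = paste0("syn:g", i))),
    list(
      pathway_entry("c1", "compound", names = "cpd:C00001"),
      pathway_entry("c2", "compound", names = "cpd:C00002")
    )
  )
  relations <- list(
    pathway_relation("1", "2", "PPrel"),
    pathway_relation("2", "3", "ECrel"),
    pathway_relation("2", "4", "PPrel"),
    pathway_relation("4", "5", "GErel"),
    pathway_relation("5", "6", "PPrel"),
    pathway_relation("5", "8", "PPrel"),
    pathway_relation("3", "c1", "PCrel"),
    pathway_relation("c1", "8", "PCrel"),
    pathway_relation("6", "c2", "PCrel"),
    pathway_relation("c2", "7", "PCrel")
  )
  pathway("syn00002", "syn", entries = entries, relations = relations)
}

# All-pairs shortest-path levels by adjacency-matrix powers: the level of
# (i, j) is the smallest k with (A^k)[i, j] > 0. Independent of any graph
# library.
matpow_levels <- function(adj) {
  n <- nrow(adj)
  out <- matrix(NA_integer_, n, n)
  acc <- diag(n)
  for (k in seq_len(n - 1L)) {
    acc <- acc %*% adj
    newly <- acc > 0 & is.na(out)
    out[newly] <- k
  }
  diag(out) <- 0L
  out
}

# Shortest-path level by exhaustive enumeration of all simple paths (DFS
# with visited set), taking the minimum length; NA when no path exists.
simple_path_level <- function(adj, a, b) {
  n <- nrow(adj)
  best <- Inf
  visit <- function(v, depth, seen) {
    if (depth >= best) return()
    for (w in seq_len(n)) {
      if (adj[v, w] > 0 && !seen[w]) {
        if (w == b) {
          best <<- min(best, depth + 1L)
        } else {
          seen[w] <- TRUE
          visit(w, depth + 1L, seen)
          seen[w] <- FALSE
        }
      }
    }
  }
  seen <- rep(FALSE, n)
  seen[a] <- TRUE
  visit(a, 0L, seen)
  if (is.infinite(best)) NA_integer_ else as.integer(best)
}

# adjacency matrix of a gene_network over a fixed gene ordering
adjacency_of <- function(net, genes = net$genes) {
  n <- length(genes)
  adj <- matrix(0L, n, n, dimnames = list(genes, genes))
  if (nrow(net$edges) > 0L) {
    i <- match(net$edges[, 1L], genes)
    j <- match(net$edges[, 2L], genes)
    adj[cbind(i, j)] <- 1L
    adj[cbind(j, i)] <- 1L
  }
  adj
}

# random simple network over k numbered genes with each pair present with
# probability p
random_net <- function(k, p = 0.4) {
  genes <- as.character(seq_len(k))
  pairs <- combn(genes, 2L)
  on <- runif(ncol(pairs)) < p
  gene_network(t(pairs[, on, drop = FALSE]), genes = genes, label = "rand")
}

# Naive validity computation straight from the definitions, using the
# matrix-power level oracle: an input edge at level l <= n adds 1/l to the
# hit weight; V = H / ||E_I||.
naive_validity <- function(input_net, gold_net, n, do_prune = TRUE) {
  edges <- input_net$edges
  if (do_prune) {
    keep <- edges[, 1L] %in% gold_net$genes & edges[, 2L] %in% gold_net$genes
    edges <- edges[keep, , drop = FALSE]
  }
  m <- nrow(edges)
  if (m == 0L) return(list(H = 0, F = 0, V = NA_real_, m = 0L))
  lev <- matpow_levels(adjacency_of(gold_net))
  h <- 0
  for (r in seq_len(m)) {
    i <- match(edges[r, 1L], gold_net$genes)
    j <- match(edges[r, 2L], gold_net$genes)
    if (is.na(i) || is.na(j)) next
    l <- lev[i, j]
    if (!is.na(l) && l >= 1L && l <= n) h <- h + 1 / l
  }
  list(H = h, F = m - h, V = h / m, m = m)
}
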