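# Sample k distinct unordered pairs uniformly from the complete graph over
# `genes`. Enumerates all pairs when that is cheap, otherwise rejection
# samples (k is far below the pair count in that regime).
sample_edge_set <- function(genes, k) {
  ng <- length(genes)
  total <- ng * (ng - 1) / 2
  if (k > total) stop(sprintf("requested %d edges but only %.0f pairs exist", k, total))
  if (k == 0L) return(matrix(character(), ncol = 2L))
  if (total <= 2e6) {
    pairs <- utils::combn(genes, 2L)
    pick <- sample.int(ncol(pairs), k)
    cbind(pairs[1L, pick], pairs[2L, pick])
  } else {
    seen <- character()
    while (length(seen) < k) {
      i <- sample.int(ng, 2L * (k - length(seen)), replace = TRUE)
      j <- sample.int(ng, 2L * (k - length(seen)), replace = TRUE)
      ok <- i != j
      key <- paste(pmin(i[ok], j[ok]), pmax(i[ok], j[ok]), sep = "-")
      seen <- unique(c(seen, key))
    }
    seen <- seen[seq_len(k)]
    idx <- do.call(rbind, strsplit(seen, "-", fixed = TRUE))
    cbind(genes[as.integer(idx[, 1L])], genes[as.integer(idx[, 2L])])
  }
}

#' Generate a null network matching a template
#'
#' Null models for ROC analysis. `pure_random` draws exactly the template's
#' edge count as a uniform sample of distinct unordered gene pairs over the
#' template's genes. `scale_free` grows a preferential-attachment graph over
#' the same genes, with the per-step attachment count chosen so the expected
#' edge count is closest to the template's (the edge count therefore need
#' not match exactly).
#'
#' @param template `gene_network` supplying gene set and edge count.
#' @param topology `"pure_random"` or `"scale_free"`.
#' @param seed Integer seed; the same seed reproduces the same network.
#' @return A `gene_network` over the template's genes.
#' @export
random_network <- function(template, topology = c("pure_random", "scale_free"), seed) {
  stopifnot(inherits(template, "gene_network"))
  topology <- match.arg(topology)
  genes <- template$genes
  if (length(genes) < 2L) stop("template must have at least 2 genes")
  ne <- nrow(template$edges)
  label <- paste0("null:", topology, ":", seed)
  withr::with_seed(as.integer(seed), {
    if (topology == "pure_random") {
      gene_network(sample_edge_set(genes, ne), genes = genes, label = label)
    } else {
      ng <- length(genes)
      # expected preferential-attachment edge count for per-step count m
      pa_edges <- function(m) sum(pmin(m, seq_len(ng - 1L)))
      m_grid <- seq_len(max(1L, ceiling(2 * ne / ng) + 1L))
      m <- m_grid[which.min(abs(vapply(m_grid, pa_edges, numeric(1)) - ne))]
      g <- igraph::simplify(igraph::sample_pa(ng, m = m, directed = FALSE))
      el <- igraph::as_edgelist(g, names = FALSE)
      perm <- sample(genes)
      gene_network(cbind(perm[el[, 1L]], perm[el[, 2L]]), genes = genes, label = label)
    }
  })
}

#' Sample size for estimating a proportion in an infinite population
#'
#' `ceil(z^2 * p * (1 - p) / margin^2)` with `z` the two-sided normal
#' quantile of the given confidence. The conventional worst case
#' (95% confidence, 5% margin, p = 0.5) yields 385, the number of null
#' networks drawn per condition in the ROC and noise studies.
#'
#' @param confidence Confidence, in (0, 1).
#' @param margin Margin of error, in (0, 1).
#' @param proportion Assumed proportion, in (0, 1); 0.5 is the worst case.
#' @return Integer sample size.
#' @export
#' @examples
#' sample_size(0.95, 0.05, 0.5) # 385
sample_size <- function(confidence = 0.95, margin = 0.05, proportion = 0.5) {
  if (!is.numeric(confidence) || confidence <= 0 || confidence >= 1) {
    stop("'confidence' must be in (0, 1)")
  }
  if (!is.numeric(margin) || margin <= 0 || margin >= 1) {
    stop("'margin' must be in (0, 1)")
  }
  if (!is.numeric(proportion) || proportion <= 0 || proportion >= 1) {
    stop("'proportion' must be in (0, 1)")
  }
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  as.integer(ceiling(z^2 * proportion * (1 - proportion) / margin^2))
}

#' Threshold grid for ROC analysis
#'
#' @param step Grid step; the default 0.01 gives the standard 101 thresholds
#'   from 0 to 1.
#' @return Numeric vector of thresholds.
#' @export
default_thresholds <- function(step = 0.01) {
  seq(0, 1, by = step)
}

#' ROC curve from positive- and negative-class scores
#'
#' At each threshold `T` an evaluation is predicted positive iff its score
#' strictly exceeds `T`; real-network evaluations are the positive class
#' and null-network evaluations the negative class, so the confusion matrix
#' at `T` is `tp = #{pos > T}`, `fn = #{pos <= T}`, `fp = #{neg > T}`,
#' `tn = #{neg <= T}`. Undefined scores (`NA`, e.g. an empty pruned
#' network) are never predicted positive. The AUC is the trapezoidal area
#' over the observed `(FPR, TPR)` points sorted by ascending FPR; no anchor
#' points are added, so a curve that never reaches `FPR = 1` is integrated
#' only over its observed range.
#'
#' @param pos_scores,neg_scores Numeric vectors of validity (or precision)
#'   scores for the positive and negative class.
#' @param thresholds Threshold grid in `[0, 1]`.
#' @return A `roc_result`: data frame `points` with columns `threshold`,
#'   `tp`, `fp`, `tn`, `fn`, `tpr`, `fpr`; the `auc`; and the `thresholds`
#'   used.
#' @export
roc_from_scores <- function(pos_scores, neg_scores, thresholds = default_thresholds()) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    stop("both score vectors must be non-empty")
  }
  if (any(thresholds < 0 | thresholds > 1)) stop("thresholds must lie in [0, 1]")
  np <- length(pos_scores)
  nn <- length(neg_scores)
  tp <- vapply(thresholds, function(t) sum(pos_scores > t, na.rm = TRUE), numeric(1))
  fp <- vapply(thresholds, function(t) sum(neg_scores > t, na.rm = TRUE), numeric(1))
  pts <- data.frame(
    threshold = thresholds,
    tp = as.integer(tp), fp = as.integer(fp),
    tn = as.integer(nn - fp), fn = as.integer(np - tp),
    tpr = tp / np, fpr = fp / nn
  )
  structure(
    list(points = pts, auc = trapezoid_auc(pts$fpr, pts$tpr), thresholds = thresholds),
    class = "roc_result"
  )
}

# Trapezoidal area under (fpr, tpr) points sorted by ascending fpr
# (ties broken by tpr); no (0,0)/(1,1) anchors are appended.
trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  x <- fpr[o]
  y <- tpr[o]
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: %d thresholds, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' ROC study of a network against null networks over a pathway panel
#'
#' Scores one real network and a set of null networks against every pathway
#' network (validity at level `n`, after pruning), then sweeps the
#' threshold grid. Each (network, pathway) pair is one evaluation: real
#' evaluations form the positive class, null evaluations the negative
#' class.
#'
#' @param real_net The inferred `gene_network` believed to carry biological
#'   signal.
#' @param pathway_nets Non-empty list of gold-standard `gene_network`s.
#' @param null_nets Non-empty list of null `gene_network`s (see
#'   [random_network()]).
#' @param n Level cap for the validity measure.
#' @param thresholds Threshold grid (default 101 values, 0 to 1 step 0.01).
#' @param scorer `"validity"` for the level-weighted measure or
#'   `"classical"` for the precision baseline; in the latter case
#'   `pathway_nets` must be a list of [pathway()] objects (or relation-only
#'   `gene_network`s).
#' @return A `roc_result`; the per-evaluation scores are attached as
#'   attributes `pos_scores` and `neg_scores`.
#' @export
roc_study <- function(real_net, pathway_nets, null_nets, n = 2L,
                      thresholds = default_thresholds(),
                      scorer = c("validity", "classical")) {
  scorer <- match.arg(scorer)
  if (length(pathway_nets) == 0L) stop("'pathway_nets' must be non-empty")
  if (length(null_nets) == 0L) stop("'null_nets' must be non-empty")
  score_one <- function(net, pw) {
    if (scorer == "validity") {
      gnv_score(net, pw, n = n, do_prune = TRUE)$validity
    } else {
      classical_precision(net, pw)
    }
  }
  pos <- vapply(pathway_nets, function(pw) score_one(real_net, pw), numeric(1))
  neg <- unlist(lapply(null_nets, function(nn) {
    vapply(pathway_nets, function(pw) score_one(nn, pw), numeric(1))
  }))
  res <- roc_from_scores(pos, neg, thresholds)
  attr(res, "pos_scores") <- pos
  attr(res, "neg_scores") <- neg
  res
}

#' Noise-degradation study of the validity measure
#'
#' At iteration `k` (noise fraction `k/10` by default), each replicate
#' removes `round(k * 0.10 * ||E||)` uniformly chosen edges of the original
#' network and adds the same number of uniformly chosen non-edges over the
#' same gene set, then scores the perturbed network against the pathway.
#' Perturbation is always applied fresh to the original network, not
#' cumulatively. A well-behaved measure degrades progressively as the noise
#' fraction grows.
#'
#' @param net Original `gene_network`.
#' @param pathway_net Gold-standard `gene_network`.
#' @param n Level cap.
#' @param iterations Number of noise steps (default 10, i.e. 10%..100%).
#' @param replicates Perturbed networks per step.
#' @param seed Integer seed.
#' @param do_prune Prune before scoring (default `TRUE`).
#' @return A `noise_profile` data frame with columns `iteration`,
#'   `noise_fraction`, `mean_validity`, `sd_validity`, `replicates`.
#' @export
noise_study <- function(net, pathway_net, n = 2L, iterations = 10L,
                        replicates = 50L, seed = 1L, do_prune = TRUE) {
  stopifnot(inherits(net, "gene_network"), inherits(pathway_net, "gene_network"))
  if (replicates < 1L) stop("'replicates' must be >= 1")
  ne <- nrow(net$edges)
  if (ne == 0L) stop("cannot perturb a network with no edges")
  keys <- edge_keys(net)
  rows <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(iterations), function(k) {
      frac <- k * 0.10
      n_swap <- min(round(frac * ne), ne)
      vals <- vapply(seq_len(replicates), function(rep) {
        if (n_swap == 0L) {
          return(gnv_score(net, pathway_net, n = n, do_prune = do_prune)$validity)
        }
        drop <- sample.int(ne, n_swap)
        kept <- net$edges[-drop, , drop = FALSE]
        kept_keys <- keys[-drop]
        # draw replacement edges from the non-edges of the current graph
        add <- matrix(character(), ncol = 2L)
        while (nrow(add) < n_swap) {
          cand <- sample_edge_set(net$genes, n_swap - nrow(add))
          ck <- paste(pmin(cand[, 1L], cand[, 2L]), pmax(cand[, 1L], cand[, 2L]), sep = "\r")
          ok <- !(ck %in% c(kept_keys, paste(add[, 1L], add[, 2L], sep = "\r"))) & !duplicated(ck)
          add <- rbind(add, cbind(pmin(cand[ok, 1L], cand[ok, 2L]),
                                  pmax(cand[ok, 1L], cand[ok, 2L])))
        }
        add <- add[seq_len(n_swap), , drop = FALSE]
        perturbed <- gene_network(rbind(kept, add), genes = net$genes,
                                  label = paste0(net$label, ":noise", k))
        gnv_score(perturbed, pathway_net, n = n, do_prune = do_prune)$validity
      }, numeric(1))
      data.frame(
        iteration = k, noise_fraction = frac,
        mean_validity = mean(vals, na.rm = TRUE),
        sd_validity = stats::sd(vals),
        replicates = replicates
      )
    })
  })
  out <- do.call(rbind, rows)
  class(out) <- c("noise_profile", class(out))
  out
}

#' Build the global network of an organism from converted pathways
#'
#' Unions the gene sets and edge sets of all converted pathway networks
#' into one organism-wide gold standard (the "KEGG global network", KGN),
#' used for whole-network evaluation before per-pathway functional
#' assignment. The operation is idempotent and order-independent.
#'
#' @param pathway_nets Non-empty list of `gene_network`s.
#' @param label Label of the result (default `"KGN"`).
#' @return A `gene_network`.
#' @export
build_kgn <- function(pathway_nets, label = "KGN") {
  if (length(pathway_nets) == 0L) stop("'pathway_nets' must be non-empty")
  stopifnot(all(vapply(pathway_nets, inherits, logical(1), "gene_network")))
  gene_network(
    do.call(rbind, lapply(pathway_nets, function(x) x$edges)),
    genes = unique(unlist(lapply(pathway_nets, function(x) x$genes))),
    label = label
  )
}

#' Rank pathways by how well they explain an input network
#'
#' Prunes and scores the input network against every pathway network and
#' ranks the pathways by descending validity; the top pathway is the
#' biological functionality that best fits the input. Pathways with
#' undefined validity (nothing left after pruning) sort last; ties are
#' broken by larger evaluated edge count, then by label.
#'
#' @param input_net Inferred `gene_network`.
#' @param pathway_nets Non-empty list of gold-standard `gene_network`s;
#'   list names (or network labels) identify the pathways.
#' @param n Level cap.
#' @return A data frame, one row per pathway in rank order, with the
#'   columns of [validity_table()]; the full `validity_result` objects are
#'   attached as attribute `results`.
#' @export
functional_assignment <- function(input_net, pathway_nets, n = 2L) {
  if (length(pathway_nets) == 0L) stop("'pathway_nets' must be non-empty")
  labels <- names(pathway_nets)
  if (is.null(labels)) labels <- vapply(pathway_nets, function(x) x$label, character(1))
  results <- lapply(pathway_nets, function(pw) gnv_score(input_net, pw, n = n, do_prune = TRUE))
  tab <- validity_table(results)
  tab$label <- labels
  v <- ifelse(is.na(tab$validity), -Inf, tab$validity)
  o <- order(-v, -tab$evaluated_edges, tab$label)
  tab <- tab[o, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "results") <- results[o]
  tab
}
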