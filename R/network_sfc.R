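# ---------------------------------------------------------------------------
# Perturbation network and the state-function cycle-closure correction
# (SFC): per-ligand absolute dG by global least squares against the
# pairwise ddG edges.
# ---------------------------------------------------------------------------

#' Construct a perturbation network
#'
#' Ligands are nodes; each directed edge (i -> j) carries the computed
#' ddG_ij = dG_j - dG_i in kcal/mol with its SEM.
#'
#' @param edges data.frame with columns `from`, `to` (node ids), `ddG`,
#'   and optionally `sem` (>= 0, default 0).
#' @param experimental optional named numeric vector of experimental dG per
#'   node (kcal/mol).
#' @return object of class `perturbation_network` with `nodes`, `edges`,
#'   `experimental`.
#' @export
perturbation_network <- function(edges, experimental = NULL) {
  stopifnot(is.data.frame(edges), all(c("from", "to", "ddG") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.null(edges$sem)) edges$sem <- 0
  if (any(edges$from == edges$to)) stop("self-edge not allowed")
  if (any(edges$sem < 0)) stop("SEM must be non-negative")
  key <- paste(edges$from, edges$to)
  if (anyDuplicated(key)) stop("duplicate directed edge")
  nodes <- sort(unique(c(edges$from, edges$to)))
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, experimental = experimental),
            class = "perturbation_network")
}

#' @export
print.perturbation_network <- function(x, ...) {
  cat(sprintf("<perturbation_network> %d node(s), %d edge(s)%s\n",
              length(x$nodes), nrow(x$edges),
              if (is.null(x$experimental)) "" else ", experimental dG attached"))
  invisible(x)
}

#' Most connected node of a network
#'
#' The network's reference ligand for the cycle-closure correction: the
#' node of maximum degree, ties broken lexicographically.
#'
#' @param net a [perturbation_network()].
#' @return node id (character).
#' @export
most_connected_node <- function(net) {
  if (!length(net$nodes)) stop("empty network")
  deg <- table(factor(c(net$edges$from, net$edges$to), levels = net$nodes))
  names(deg)[which.max(deg)]  # which.max takes the first (lexicographic) max
}

network_components <- function(net) {
  idx <- seq_along(net$nodes)
  names(idx) <- net$nodes
  parent <- idx
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(net$edges))) {
    a <- find(idx[[net$edges$from[k]]]); b <- find(idx[[net$edges$to[k]]])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(idx, find, integer(1))
  split(net$nodes, roots)
}

#' State-function cycle-closure correction (SFC)
#'
#' Free energy is a state function, so the net change around any closed
#' cycle of the network must vanish; raw pairwise estimates generally
#' violate this. The correction assigns each ligand an absolute value g_i
#' minimizing sum over edges of w_e * (g_j - g_i - ddG_ij)^2, anchored at
#' the reference node (by convention the most connected ligand). Edges are
#' unweighted by default; `weighted = TRUE` uses inverse-variance weights
#' 1/sem^2.
#'
#' @param net a connected [perturbation_network()].
#' @param reference reference node id, or `"auto"` for
#'   [most_connected_node()].
#' @param anchor value assigned to the reference node (default 0); with
#'   `anchor = "experimental"` node values are shifted so
#'   mean(predicted) = mean(experimental) over nodes with experimental
#'   data.
#' @param weighted inverse-variance edge weighting.
#' @return object of class `node_free_energies`: data.frame `nodes`
#'   (`node`, `dG`, `n_edges`), `reference`, and per-edge `residuals`
#'   (ddG_corrected - ddG_input).
#' @export
sfc_correct <- function(net, reference = "auto", anchor = 0,
                        weighted = FALSE) {
  stopifnot(inherits(net, "perturbation_network"))
  comps <- network_components(net)
  if (length(comps) > 1L)
    stop("network is disconnected; components: ",
         paste(vapply(comps, paste, "", collapse = "+"), collapse = " | "))
  if (identical(reference, "auto")) reference <- most_connected_node(net)
  if (!reference %in% net$nodes) stop("reference node not in network")
  n <- length(net$nodes)
  e <- nrow(net$edges)
  iA <- match(net$edges$from, net$nodes)
  iB <- match(net$edges$to, net$nodes)
  A <- matrix(0, e, n)
  A[cbind(seq_len(e), iA)] <- -1
  A[cbind(seq_len(e), iB)] <- 1
  d <- net$edges$ddG
  if (weighted) {
    w <- 1 / pmax(net$edges$sem, 1e-6)^2
    A <- A * sqrt(w)
    d <- d * sqrt(w)
  }
  ref_col <- match(reference, net$nodes)
  Ar <- A[, -ref_col, drop = FALSE]
  qrA <- qr(Ar)
  g_free <- if (qrA$rank < ncol(Ar)) {
    warning(sprintf("near-singular incidence system (rank %d of %d); using pseudo-inverse",
                    qrA$rank, ncol(Ar)))
    MASS::ginv(Ar) %*% d
  } else qr.coef(qrA, d)
  g <- numeric(n)
  g[-ref_col] <- as.numeric(g_free)
  g[ref_col] <- 0
  if (identical(anchor, "experimental")) {
    if (is.null(net$experimental)) stop("no experimental values attached")
    common <- intersect(net$nodes, names(net$experimental))
    if (!length(common)) stop("no node has experimental data")
    shift <- mean(net$experimental[common]) - mean(g[match(common, net$nodes)])
    g <- g + shift
  } else {
    g <- g + as.numeric(anchor)
  }
  corrected <- g[iB] - g[iA]
  deg <- table(factor(c(net$edges$from, net$edges$to), levels = net$nodes))
  structure(list(
    nodes = data.frame(node = net$nodes, dG = g,
                       n_edges = as.integer(deg[net$nodes])),
    reference = reference,
    residuals = data.frame(from = net$edges$from, to = net$edges$to,
                           residual = corrected - net$edges$ddG)),
    class = "node_free_energies")
}

#' @export
print.node_free_energies <- function(x, ...) {
  cat(sprintf("<node_free_energies> %d node(s), reference %s, max |edge residual| %.3g kcal/mol\n",
              nrow(x$nodes), x$reference, max(abs(x$residuals$residual), 0)))
  invisible(x)
}

#' Cycle-consistent corrected edge values
#'
#' Re-expresses every edge from the fitted node values:
#' ddG_corrected(i -> j) = dG_j - dG_i. By construction these sum to zero
#' around every cycle to machine precision and are exactly antisymmetric.
#'
#' @param nfe a [sfc_correct()] result.
#' @param net the network it was fitted to.
#' @return the network's edge table with `ddG_corrected` and `residual`
#'   columns appended.
#' @export
corrected_edges <- function(nfe, net) {
  g <- structure(nfe$nodes$dG, names = nfe$nodes$node)
  out <- net$edges
  out$ddG_corrected <- as.numeric(g[out$to] - g[out$from])
  out$residual <- out$ddG_corrected - out$ddG
  out
}

#' Read a network edge-list CSV (ligA, ligB, ddG, sem)
#' @param path CSV path.
#' @param experimental optional CSV path with columns `ligand`, `dG`.
#' @return a [perturbation_network()].
#' @export
read_network <- function(path, experimental = NULL) {
  tab <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  names(tab)[1:2] <- c("from", "to")
  names(tab)[names(tab) == "ddg"] <- "ddG"
  exp_v <- NULL
  if (!is.null(experimental)) {
    ex <- read.table(experimental, header = TRUE, sep = ",",
                     stringsAsFactors = FALSE)
    exp_v <- structure(as.numeric(ex[[2]]), names = as.character(ex[[1]]))
  }
  perturbation_network(tab, exp_v)
}

#' Write node free energies as CSV (ligand, dG, n_edges, max residual)
#' @param nfe a [sfc_correct()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_node_energies <- function(nfe, path) {
  res <- nfe$residuals
  max_res <- vapply(nfe$nodes$node, function(nd) {
    r <- abs(res$residual[res$from == nd | res$to == nd])
    if (length(r)) max(r) else 0
  }, numeric(1))
  out <- data.frame(ligand = nfe$nodes$node, dG = nfe$nodes$dG,
                    n_edges = nfe$nodes$n_edges, max_residual = max_res)
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
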