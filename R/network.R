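# Thresholded epistasis graphs, threshold sweeps, components, degrees.
#
# A network G_t links two SNPs whenever their information gain is >= t
# (ties at exactly t included); only SNPs incident to at least one edge
# are vertices, so isolated SNPs are never graph members. As t decreases
# the graphs nest: G_t2 is a subgraph of G_t1 for t1 < t2.

#' Build the epistasis network at a threshold
#'
#' Edge set: all pairs with `ig >= t`. Vertex set: the endpoints of those
#' edges (degree >= 1 by construction). Vertices carry the
#' `mutual_information` main-effect attribute when `mains` is supplied;
#' edges carry `information_gain` and, if present in `pw`, `p_value`.
#'
#' @param pw a [pair_weights()] table.
#' @param mains optional [main_effects()] table for vertex weights.
#' @param threshold finite edge-inclusion threshold `t`.
#' @return An undirected [igraph::igraph] with graph attribute
#'   `threshold`.
#' @export
build_graph <- function(pw, mains = NULL, threshold) {
  if (!is.finite(threshold) && threshold != -Inf)
    stop_validation("threshold must be finite or -Inf")
  sel <- pw$ig >= threshold
  ed <- pw[sel, , drop = FALSE]
  if (nrow(ed) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    verts <- sort(unique(c(ed$snp_a, ed$snp_b)))
    vdf <- data.frame(name = verts, stringsAsFactors = FALSE)
    if (!is.null(mains)) vdf$mutual_information <- as.numeric(mains[verts])
    edf <- data.frame(from = ed$snp_a, to = ed$snp_b,
                      information_gain = ed$ig, stringsAsFactors = FALSE)
    if ("p_value" %in% names(ed)) edf$p_value <- ed$p_value
    g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  }
  igraph::graph_attr(g, "threshold") <- threshold
  g
}

#' Keep only permutation-significant edges
#'
#' The significance-filtered network keeps edges whose permutation
#' p-value is at most `alpha` (default 0.01) and drops vertices left with
#' degree zero. Idempotent at fixed `alpha`.
#'
#' @param g an epistasis graph whose edges carry `p_value`.
#' @param alpha per-edge significance level.
#' @return The filtered [igraph::igraph].
#' @export
filter_significant <- function(g, alpha = 0.01) {
  p <- igraph::edge_attr(g, "p_value")
  if (igraph::ecount(g) > 0L && (is.null(p) || anyNA(p)))
    stop_validation("edges lack p_value; run pair_pvalues() before filtering")
  if (igraph::ecount(g) > 0L)
    g <- igraph::delete_edges(g, which(p > alpha))
  igraph::delete_vertices(g, which(igraph::degree(g) == 0L))
}

#' Descending threshold grid
#'
#' `t_max, t_max - step, ...` down to `t_min`, snapped to 12 decimals so
#' floating-point drift never drops a grid point.
#'
#' @param t_max,t_min,step grid limits and decrement.
#' @return Numeric vector of thresholds, descending.
#' @export
threshold_grid <- function(t_max, t_min, step) {
  if (t_max < t_min) stop_validation("t_max (%g) < t_min (%g)", t_max, t_min)
  if (step <= 0) stop_validation("step must be positive, got %g", step)
  k <- 0:floor((t_max - t_min) / step + 1e-9)
  round(t_max - k * step, 12)
}

# Per-threshold summary of one weight vector without materialising
# igraph objects per threshold beyond component finding. Returns a list:
# stats data.frame + component-size list + degree-count list.
sweep_stats <- function(ii, jj, w, grid) {
  n_edges <- integer(length(grid))
  n_vertices <- integer(length(grid))
  lcc <- integer(length(grid))
  comp_sizes <- vector("list", length(grid))
  deg_counts <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    sel <- w >= grid[k]
    ne <- sum(sel)
    n_edges[k] <- ne
    if (ne == 0L) {
      comp_sizes[[k]] <- integer(0)
      deg_counts[[k]] <- integer(0)
      next
    }
    el <- cbind(ii[sel], jj[sel])
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    cs <- igraph::components(g)$csize
    cs <- sort(cs[cs >= 2L], decreasing = TRUE)  # size-1 comps = isolated ids
    comp_sizes[[k]] <- cs
    n_vertices[k] <- sum(cs)
    lcc[k] <- cs[1]
    dg <- igraph::degree(g)
    dg <- dg[dg > 0L]
    tb <- table(dg)
    deg_counts[[k]] <- stats::setNames(as.integer(tb), names(tb))
  }
  list(stats = data.frame(threshold = grid, n_edges = n_edges,
                          n_vertices = n_vertices, lcc_size = lcc),
       components = comp_sizes, degrees = deg_counts)
}

#' Sweep the network over a descending threshold grid
#'
#' Builds `G_t` for `t = t_max, t_max - step, ..., t_min` and records per
#' threshold the edge count, vertex count and connected-component sizes.
#' Monotone nesting (edge and vertex sets grow as `t` decreases) is
#' asserted on the result.
#'
#' @param pw a [pair_weights()] table.
#' @param t_max,t_min,step grid limits and decrement (defaults 0.02, 0,
#'   0.001 — the scan used to locate the interesting threshold band).
#' @return A data frame of class `threshold_sweep` with columns
#'   `threshold`, `n_edges`, `n_vertices`, `lcc_size`; attributes
#'   `components` (list of descending component-size vectors) and
#'   `degrees` (list of degree-count tables).
#' @export
threshold_sweep <- function(pw, t_max = 0.02, t_min = 0, step = 0.001) {
  grid <- threshold_grid(t_max, t_min, step)
  res <- sweep_stats(pw$i, pw$j, pw$ig, grid)
  st <- res$stats
  if (is.unsorted(st$n_edges) || is.unsorted(st$n_vertices))
    stop("internal error: nesting violated across the threshold grid")
  structure(st, components = res$components, degrees = res$degrees,
            class = c("threshold_sweep", "data.frame"))
}

#' Connected components of an epistasis graph
#'
#' @param g an [igraph::igraph].
#' @return A list of character vectors of vertex names, ordered by
#'   decreasing size; ties broken by the lexicographically smallest
#'   member.
#' @export
graph_components <- function(g) {
  if (igraph::vcount(g) == 0L) return(list())
  comp <- igraph::components(g)
  parts <- split(igraph::V(g)$name, comp$membership)
  parts <- lapply(parts, sort)
  ord <- order(-vapply(parts, length, integer(1)),
               vapply(parts, `[`, character(1), 1L))
  unname(parts[ord])
}

#' Vertex degree distribution of an epistasis graph
#'
#' Counts over member vertices only; by construction every vertex has
#' degree at least 1, so the handshake identity
#' `sum(d * n(d)) = 2 * |E|` holds.
#'
#' @param g an [igraph::igraph] whose vertices all have degree >= 1.
#' @return An object of class `degree_distribution_table`: list with
#'   `degree` (sorted distinct degrees), `count`, `p` (fractions) and
#'   `n_vertices`.
#' @export
degree_dist <- function(g) {
  d <- igraph::degree(g)
  if (any(d == 0L))
    stop_validation("graph has degree-zero vertices; not an epistasis network")
  tb <- table(d)
  degree_dist_from_counts(as.integer(names(tb)), as.integer(tb))
}

#' @rdname degree_dist
#' @param degree,count parallel vectors of distinct degrees (>= 1) and
#'   their vertex counts, e.g. transcribed from a published degree
#'   distribution table.
#' @export
degree_dist_from_counts <- function(degree, count) {
  degree <- as.integer(degree)
  count <- as.integer(count)
  if (length(degree) != length(count))
    stop_validation("degree and count lengths differ")
  keep <- count > 0L
  degree <- degree[keep]
  count <- count[keep]
  if (any(degree < 1L)) stop_validation("degrees must be >= 1")
  if (anyDuplicated(degree)) stop_validation("duplicate degree values")
  ord <- order(degree)
  degree <- degree[ord]
  count <- count[ord]
  n <- sum(count)
  structure(list(degree = degree, count = count, p = count / n, n_vertices = n),
            class = "degree_distribution_table")
}

#' @export
print.degree_distribution_table <- function(x, ...) {
  cat(sprintf("degree distribution: %d vertices, %d edges, degrees %s\n",
              x$n_vertices, sum(x$degree * x$count) / 2,
              paste(x$degree, collapse = ",")))
  invisible(x)
}

#' Number of edges implied by a degree distribution
#'
#' Handshake lemma: `|E| = sum(d * n(d)) / 2`.
#'
#' @param dd a [degree_dist()] object.
#' @return The edge count.
#' @export
edges_from_degrees <- function(dd) sum(dd$degree * dd$count) / 2

# ---- export formats ---------------------------------------------------

#' Export an epistasis graph
#'
#' `write_edge_table()`/`write_vertex_table()` emit the plain TSV edge
#' and vertex lists; `write_graphml()` emits GraphML with the
#' `mutual_information`, `information_gain` and `p_value` attributes
#' (re-importable with [read_graphml()]); `write_dot()` emits Graphviz
#' DOT in which vertex size is proportional to the main effect and edge
#' penwidth to the information gain, with the scaling factors recorded
#' in header comments.
#'
#' @param g an epistasis graph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(extra = sprintf("threshold=%g",
                                               igraph::graph_attr(g, "threshold") %||% NA)), con)
  has_p <- !is.null(igraph::edge_attr(g, "p_value"))
  writeLines(paste(c("snp_a", "snp_b", "information_gain",
                     if (has_p) "p_value"), collapse = "\t"), con)
  if (igraph::ecount(g) > 0L) {
    el <- igraph::as_edgelist(g)
    body <- sprintf("%s\t%s\t%.17g", el[, 1], el[, 2],
                    igraph::E(g)$information_gain)
    if (has_p) body <- sprintf("%s\t%.17g", body, igraph::E(g)$p_value)
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname write_edge_table
#' @export
write_vertex_table <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(), con)
  writeLines("snp_id\tmutual_information\tdegree", con)
  if (igraph::vcount(g) > 0L) {
    mi <- igraph::vertex_attr(g, "mutual_information") %||%
      rep(NA_real_, igraph::vcount(g))
    writeLines(sprintf("%s\t%.17g\t%d", igraph::V(g)$name, mi,
                       igraph::degree(g)), con)
  }
  invisible(path)
}

#' @rdname write_edge_table
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_edge_table
#' @export
read_graphml <- function(path) igraph::read_graph(path, format = "graphml")

#' @rdname write_edge_table
#' @param max_vertex_size,max_penwidth largest rendered vertex size /
#'   edge width; the strongest main effect and information gain map onto
#'   these.
#' @export
write_dot <- function(g, path, max_vertex_size = 2, max_penwidth = 5) {
  mi <- igraph::vertex_attr(g, "mutual_information")
  if (!is.null(mi) && length(mi) && max(mi) > 0) {
    v_scale <- max_vertex_size / max(mi)
    igraph::V(g)$width <- pmax(mi * v_scale, 0.05)
  } else v_scale <- NA_real_
  ig <- igraph::edge_attr(g, "information_gain")
  if (!is.null(ig) && length(ig) && max(ig) > 0) {
    e_scale <- max_penwidth / max(ig)
    igraph::E(g)$penwidth <- pmax(ig * e_scale, 0.1)
  } else e_scale <- NA_real_
  tmp <- tempfile(fileext = ".dot")
  igraph::write_graph(g, tmp, format = "dot")
  body <- readLines(tmp, warn = FALSE)
  unlink(tmp)
  hdr <- c(sprintf("// episnet %s", as.character(utils::packageVersion("episnet"))),
           sprintf("// vertex width = mutual_information * %.6g (inches)", v_scale),
           sprintf("// edge penwidth = information_gain * %.6g", e_scale))
  writeLines(c(hdr, body), path)
  invisible(path)
}
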