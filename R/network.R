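#' Average fragment metric cubes to colony level
#'
#' @param cubes List of `metric_cube` objects (one per fragment).
#' @param colony_map Data.frame with `sample_id` and `colony`.
#' @return List: `means` (colonies x metrics matrix, missing-aware mean)
#'   and `n` (contributing fragment counts).
#' @export
average_replicates <- function(cubes, colony_map) {
  wide <- cubes_to_wide(cubes)
  colony <- colony_map$colony[match(rownames(wide), colony_map$sample_id)]
  if (anyNA(colony)) {
    stop("fragment(s) with unknown colony: ",
         paste(rownames(wide)[is.na(colony)], collapse = ", "))
  }
  colonies <- unique(colony)
  means <- matrix(NA_real_, length(colonies), ncol(wide),
                  dimnames = list(colonies, colnames(wide)))
  ns <- means
  for (cl in colonies) {
    block <- wide[colony == cl, , drop = FALSE]
    means[cl, ] <- colMeans(block, na.rm = TRUE)
    ns[cl, ] <- colSums(is.finite(block))
  }
  means[!is.finite(means)] <- NA_real_
  list(means = means, n = ns)
}

#' Correlate colony-level metrics with cellular traits
#'
#' Pearson correlation between every (metric, trait) pair across colonies;
#' pairs with |r| strictly above the threshold become signed edges of the
#' trait network. Zero-variance columns are skipped and logged in
#' `skipped`.
#'
#' @param colony_metrics Colonies x metrics matrix ([average_replicates()]
#'   `$means`).
#' @param colony_traits Data.frame with `colony` and numeric trait columns
#'   (rows matched to the metric matrix by colony).
#' @param threshold Retention threshold on |r| (strict).
#' @param trait_cols Trait columns to use; default all numeric.
#' @return Object of class `trait_network`: `edges` (trait, metric, r,
#'   sign, n), `threshold`, `traits`, `n_colonies`, `skipped`.
#' @export
correlate_traits <- function(colony_metrics, colony_traits,
                             threshold = 0.6, trait_cols = NULL) {
  stopifnot(nrow(colony_metrics) >= 5L)
  idx <- match(rownames(colony_metrics), colony_traits$colony)
  if (anyNA(idx)) stop("colonies missing from the trait table")
  if (is.null(trait_cols)) {
    trait_cols <- setdiff(
      names(colony_traits)[vapply(colony_traits, is.numeric, logical(1))],
      c("fragment", "seed"))
  }
  tr <- as.matrix(colony_traits[idx, trait_cols, drop = FALSE])
  skipped <- character(0)
  edges <- NULL
  for (j in seq_len(ncol(tr))) {
    tj <- tr[, j]
    if (stats::sd(tj, na.rm = TRUE) == 0 || all(is.na(tj))) {
      skipped <- c(skipped, trait_cols[j])
      next
    }
    ok_t <- is.finite(tj)
    r <- suppressWarnings(
      stats::cor(tj, colony_metrics, use = "pairwise.complete.obs"))[1, ]
    n <- colSums(is.finite(colony_metrics) & ok_t)
    keep <- is.finite(r) & abs(r) > threshold & n >= 3L
    if (any(keep)) {
      edges <- rbind(edges, data.frame(
        trait = trait_cols[j],
        metric = colnames(colony_metrics)[keep],
        r = unname(r[keep]),
        sign = ifelse(r[keep] > 0, "positive", "negative"),
        n = unname(n[keep])))
    }
  }
  sk2 <- colnames(colony_metrics)[apply(colony_metrics, 2L, function(x)
    stats::sd(x, na.rm = TRUE) == 0 || all(is.na(x)))]
  structure(list(edges = edges, threshold = threshold,
                 traits = trait_cols,
                 n_colonies = nrow(colony_metrics),
                 skipped = c(skipped, sk2)),
            class = "trait_network")
}

#' @export
print.trait_network <- function(x, ...) {
  ne <- if (is.null(x$edges)) 0L else nrow(x$edges)
  cat("Trait network: ", ne, " edges with |r| > ", x$threshold,
      " over ", x$n_colonies, " colonies\n", sep = "")
  if (ne > 0) {
    tab <- table(x$edges$trait, x$edges$sign)
    print(tab)
  }
  invisible(x)
}

#' Summarize edges per trait
#'
#' @param network A [correlate_traits()] result.
#' @return Data.frame: trait, edges, positive, negative.
#' @export
network_summary <- function(network) {
  e <- network$edges
  if (is.null(e) || nrow(e) == 0L) {
    return(data.frame(trait = character(0), edges = integer(0),
                      positive = integer(0), negative = integer(0)))
  }
  out <- do.call(rbind, lapply(split(e, e$trait), function(d) {
    data.frame(trait = d$trait[1], edges = nrow(d),
               positive = sum(d$sign == "positive"),
               negative = sum(d$sign == "negative"))
  }))
  rownames(out) <- NULL
  out[order(-out$edges), ]
}

# build the igraph object shared by the exporters
network_igraph <- function(network) {
  e <- network$edges
  verts <- data.frame(
    name = c(unique(e$trait), unique(e$metric)),
    kind = c(rep("trait", length(unique(e$trait))),
             rep("metric", length(unique(e$metric)))))
  verts$family <- ifelse(verts$kind == "metric",
                         sub("_.*$", "", verts$name), NA_character_)
  igraph::graph_from_data_frame(
    e[, c("trait", "metric", "r", "sign", "n")],
    directed = FALSE, vertices = verts)
}

#' Export a trait network
#'
#' @param network A [correlate_traits()] result.
#' @param path Output file.
#' @param format `"graphml"` or `"edgelist"` (tab-delimited edge table).
#' @param allow_empty Permit writing an empty network.
#' @return The path, invisibly.
#' @export
export_graph <- function(network, path,
                         format = c("graphml", "edgelist"),
                         allow_empty = FALSE) {
  format <- match.arg(format)
  e <- network$edges
  if ((is.null(e) || nrow(e) == 0L) && !allow_empty) {
    stop("refusing to export an empty network (set allow_empty = TRUE)")
  }
  if (format == "graphml") {
    g <- if (is.null(e) || nrow(e) == 0L) {
      igraph::make_empty_graph(directed = FALSE)
    } else {
      network_igraph(network)
    }
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.table(
      if (is.null(e)) data.frame() else e, path,
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GraphML trait network back into an edge table
#'
#' @param path GraphML file written by [export_graph()].
#' @return Data.frame with trait, metric, r, sign, n.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::ecount(g) == 0L) {
    return(data.frame(trait = character(0), metric = character(0),
                      r = numeric(0), sign = character(0), n = integer(0)))
  }
  ends <- igraph::as_edgelist(g)
  kind <- igraph::vertex_attr(g, "kind")
  names(kind) <- igraph::vertex_attr(g, "name")
  trait_first <- kind[ends[, 1]] == "trait"
  data.frame(
    trait = ifelse(trait_first, ends[, 1], ends[, 2]),
    metric = ifelse(trait_first, ends[, 2], ends[, 1]),
    r = igraph::edge_attr(g, "r"),
    sign = igraph::edge_attr(g, "sign"),
    n = as.integer(igraph::edge_attr(g, "n")))
}
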