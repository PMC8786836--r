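#' Per-gene expression specificity across clusters
#'
#' Cluster-mean expression divided by the median of the cluster means: ~1
#' for a uniformly expressed gene, large in the cluster where a specific
#' gene peaks.
#'
#' @param expression Cells x genes matrix.
#' @param clusters Per-cell cluster labels.
#' @return Tibble: `gene`, `cluster`, `specificity`.
#' @export
expression_specificity <- function(expression, clusters) {
  E <- as_dense(expression)
  labs <- sort(unique(as.character(clusters)))
  cl_mean <- sapply(labs, function(l) {
    colMeans(E[as.character(clusters) == l, , drop = FALSE])
  })
  if (is.null(dim(cl_mean))) cl_mean <- matrix(cl_mean, ncol = length(labs),
                                               dimnames = list(colnames(E), labs))
  med <- apply(cl_mean, 1, median)
  spec <- cl_mean / ifelse(med > 0, med, 1)
  as_tibble(as.data.frame.table(spec, responseName = "specificity",
                                stringsAsFactors = FALSE)) |>
    dplyr::rename(gene = "Var1", cluster = "Var2")
}

#' Network statistics of a pruned cluster GRN
#'
#' Directed betweenness centrality (number of shortest source-target paths a
#' node lies on, unweighted and unnormalized), outdegree, and optionally
#' expression specificity of each node.
#'
#' @param grn A [fit_cluster_grn()] object, or an edge tibble with
#'   `regulator`, `target` (and optionally `cluster`) columns.
#' @param expression,clusters Optional; when both are given, a `specificity`
#'   column (the gene's specificity in the GRN's own cluster) is added.
#' @return Tibble: `cluster`, `gene`, `outdegree`, `betweenness`
#'   (+ `specificity`).
#' @export
network_stats <- function(grn, expression = NULL, clusters = NULL) {
  edges <- if (inherits(grn, "cluster_grn")) tidy(grn) else as_tibble(grn)
  if (!nrow(edges)) {
    return(tibble(cluster = character(), gene = character(),
                  outdegree = numeric(), betweenness = numeric()))
  }
  if (!"cluster" %in% names(edges)) edges$cluster <- "all"
  spec <- if (!is.null(expression) && !is.null(clusters)) {
    expression_specificity(expression, clusters)
  }
  out <- lapply(split(edges, edges$cluster), function(e) {
    g <- igraph::graph_from_data_frame(e[, c("regulator", "target")],
                                       directed = TRUE)
    res <- tibble(cluster = e$cluster[1],
                  gene = igraph::V(g)$name,
                  outdegree = as.numeric(igraph::degree(g, mode = "out")),
                  betweenness = as.numeric(igraph::betweenness(g, directed = TRUE,
                                                               normalized = FALSE)))
    if (!is.null(spec)) {
      res <- left_join(res, dplyr::filter(spec, .data$cluster == e$cluster[1]),
                       by = c("gene", "cluster"))
    }
    res
  })
  bind_rows(out)
}

#' Rank regulators by focus-set intersection and extract the top subgraph
#'
#' Edges below the weight cutoff are dropped; regulators are ranked by the
#' size of the intersection of their target sets with a focus gene list
#' (descending, ties broken lexicographically). The induced subgraph of the
#' top `top_n` regulators is partitioned into communities (Leiden by
#' default, resolution 2) and, when expression is supplied, each community's
#' mean expression per cluster ("subnetwork activity") is reported.
#'
#' @param edges Edge tibble with `regulator`, `target`, `weight`.
#' @param focus_genes Non-empty character vector of focus genes.
#' @param top_n Number of top regulators in the subgraph (default 200).
#' @param weight_cutoff Minimum edge weight retained (default 0.01).
#' @param resolution Resolution of the community partition (default 2).
#' @param partitioner Optional function(graph, resolution) returning a
#'   community membership vector; defaults to Leiden on the undirected graph.
#' @param expression,clusters Optional cells x genes matrix and labels for
#'   subnetwork activity.
#' @param seed Seed for the (stochastic) partitioner.
#' @return Object of class `regulator_ranking`: `ranking` (tibble
#'   `regulator`, `n_focus_targets`, `rank`), `communities` (tibble
#'   `regulator`, `community`), `activity` (tibble `community`, `cluster`,
#'   `activity`, or `NULL`), and the igraph `subgraph`.
#' @export
rank_regulators <- function(edges, focus_genes, top_n = 200,
                            weight_cutoff = 0.01, resolution = 2,
                            partitioner = NULL, expression = NULL,
                            clusters = NULL, seed = 1L) {
  edges <- as_tibble(edges)
  require_columns(edges, c("regulator", "target", "weight"), "edges")
  if (!length(focus_genes)) abort("`focus_genes` must be non-empty.")
  edges <- dplyr::filter(edges, abs(.data$weight) >= weight_cutoff)

  ranking <- edges |>
    group_by(.data$regulator) |>
    summarise(n_focus_targets = length(intersect(unique(.data$target), focus_genes)),
              .groups = "drop") |>
    arrange(desc(.data$n_focus_targets), .data$regulator) |>
    mutate(rank = row_number())

  top <- head(ranking$regulator, top_n)
  sub_edges <- dplyr::filter(edges, .data$regulator %in% top, .data$target %in% top)
  g <- igraph::graph_from_data_frame(sub_edges[, c("regulator", "target")],
                                     directed = FALSE,
                                     vertices = tibble(name = top))
  membership <- with_seed_local(seed, {
    if (is.null(partitioner)) {
      igraph::membership(igraph::cluster_leiden(
        igraph::simplify(g), objective_function = "CPM",
        resolution = resolution))
    } else {
      partitioner(g, resolution)
    }
  })
  communities <- tibble(regulator = top,
                        community = as.integer(membership[top]))

  activity <- NULL
  if (!is.null(expression) && !is.null(clusters)) {
    E <- as_dense(expression)
    labs <- sort(unique(as.character(clusters)))
    activity <- communities |>
      dplyr::filter(.data$regulator %in% colnames(E)) |>
      group_by(.data$community) |>
      dplyr::group_modify(function(df, key) {
        vals <- vapply(labs, function(l) {
          mean(E[as.character(clusters) == l, df$regulator, drop = FALSE])
        }, numeric(1))
        tibble(cluster = labs, activity = unname(vals))
      }) |>
      ungroup()
  }
  structure(list(ranking = ranking, communities = communities,
                 activity = activity, subgraph = g),
            class = "regulator_ranking")
}

#' @export
print.regulator_ranking <- function(x, ...) {
  cat(sprintf("Regulator ranking: %d regulators, top subgraph of %d in %d communities\n",
              nrow(x$ranking), nrow(x$communities),
              length(unique(x$communities$community))))
  invisible(x)
}
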