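# Export of module-level results: graphs, spatial weight tables, figures.

#' Export a module-level eigenconnectivity matrix as a graph
#'
#' Writes the K x K module-level matrix G as an undirected graph with
#' self-loops: one node per module, one edge per upper-triangular entry
#' (including the diagonal), edge weight `g_kl^2` and a color attribute
#' encoding the sign of `g_kl`. The global sign of G is first fixed to
#' maximize the summed squares of its positive entries. Both a Graphviz DOT
#' file and a JSON file (which round-trips G up to that global sign) are
#' written.
#'
#' @param G K x K symmetric module-level eigenconnectivity matrix.
#' @param path output path without extension; `<path>.dot` and
#'   `<path>.json` are written.
#' @param module_names optional K module names.
#' @return invisibly, a tibble of the exported edges (`from`, `to`,
#'   `weight`, `sign`).
#' @export
export_module_graph <- function(G, path, module_names = NULL) {
  G <- as.matrix(G)
  K <- nrow(G)
  stopifnot(ncol(G) == K)
  if (!is_symmetric_tol(G, 1e-8)) stop("G must be symmetric", call. = FALSE)
  if (sum(pmax(-G, 0)^2) > sum(pmax(G, 0)^2)) G <- -G
  if (is.null(module_names)) module_names <- paste0("module", seq_len(K))
  idx <- which(upper.tri(G, diag = TRUE), arr.ind = TRUE)
  idx <- idx[G[idx] != 0, , drop = FALSE]   # zero entries draw no edge
  edges <- tibble::tibble(
    from = module_names[idx[, 1]], to = module_names[idx[, 2]],
    weight = G[idx]^2, sign = sign_pos(G[idx]))
  dot <- c("graph modules {",
           sprintf("  \"%s\";", module_names),
           sprintf("  \"%s\" -- \"%s\" [penwidth=%.6g, color=\"%s\", weight=%.6g];",
                   edges$from, edges$to, pmax(10 * edges$weight, 0.1),
                   ifelse(edges$sign >= 0, "orange", "purple"),
                   edges$weight),
           "}")
  writeLines(dot, paste0(path, ".dot"))
  jsonlite::write_json(
    list(modules = module_names, G = unname(G),
         edges = list(from = edges$from, to = edges$to,
                      weight = edges$weight, sign = edges$sign)),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(edges)
}

#' Read back a module graph JSON export
#'
#' @param path path to a `.json` file written by [export_module_graph()].
#' @return the stored G matrix (sign-fixed as exported).
#' @export
read_module_graph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as.matrix(obj$G)
}

#' Export module weights with node coordinates
#'
#' Writes one TSV per module with columns `node_id`, `weight`, `x`, `y`,
#' `z` and optionally returns a dot-plot figure showing every node
#' projected onto the three orthogonal planes (right-lateral view: y-z,
#' dorsal view: x-y, posterior view: x-z), with dot area and color
#' intensity scaled to the weight magnitude, rescaled within each module,
#' and color encoding the sign (red positive, blue negative).
#'
#' @param W D x K module weight matrix with node labels as row names (or
#'   supply `node_labels`).
#' @param coords coordinate tibble from [read_roi_coordinates()] covering
#'   every node with a nonzero weight.
#' @param path output path without extension; `<path>_module<k>.tsv` files
#'   are written.
#' @param node_labels optional D node labels overriding `rownames(W)`.
#' @param plot if `TRUE`, also return a ggplot of the three views.
#' @return invisibly, a tibble of all exported rows (`module`, `node_id`,
#'   `weight`, `x`, `y`, `z`); with `plot = TRUE` the tibble carries the
#'   ggplot in attribute `"plot"`.
#' @export
export_spatial_weights <- function(W, coords, path, node_labels = NULL,
                                   plot = FALSE) {
  W <- as.matrix(W)
  if (is.null(node_labels)) node_labels <- rownames(W)
  if (is.null(node_labels)) node_labels <- paste0("node", seq_len(nrow(W)))
  weighted <- node_labels[rowSums(W != 0) > 0]
  missing <- setdiff(weighted, coords$node_id)
  if (length(missing) > 0) {
    stop("missing coordinates for weighted node(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  pos <- match(node_labels, coords$node_id)
  rows <- lapply(seq_len(ncol(W)), function(k) {
    tab <- tibble::tibble(module = k, node_id = node_labels,
                          weight = W[, k],
                          x = coords$x[pos], y = coords$y[pos],
                          z = coords$z[pos])
    utils::write.table(tab, sprintf("%s_module%d.tsv", path, k),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tab
  })
  out <- dplyr::bind_rows(rows)
  if (plot) {
    views <- dplyr::bind_rows(
      dplyr::mutate(out, h = .data$y, v = .data$z, view = "right lateral"),
      dplyr::mutate(out, h = .data$x, v = .data$y, view = "dorsal"),
      dplyr::mutate(out, h = .data$x, v = .data$z, view = "posterior"))
    views <- dplyr::mutate(
      dplyr::group_by(views, .data$module),
      rel = abs(.data$weight) / max(abs(.data$weight), 1e-300))
    p <- ggplot2::ggplot(dplyr::ungroup(views),
                         ggplot2::aes(x = .data$h, y = .data$v,
                                      size = .data$rel,
                                      alpha = .data$rel,
                                      color = factor(sign(.data$weight)))) +
      ggplot2::geom_point() +
      ggplot2::facet_grid(module ~ view) +
      ggplot2::scale_color_manual(
        values = c("-1" = "blue", "0" = "grey80", "1" = "red"),
        name = "sign") +
      ggplot2::scale_size_area(max_size = 4, guide = "none") +
      ggplot2::scale_alpha(range = c(0.1, 1), guide = "none") +
      ggplot2::coord_equal() +
      ggplot2::labs(x = NULL, y = NULL) +
      ggplot2::theme_minimal()
    attr(out, "plot") <- p
  }
  invisible(out)
}

#' Export an eigenvalue spectrum as TSV
#'
#' @param spectrum tibble from [eigen_spectrum()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_spectrum <- function(spectrum, path) {
  utils::write.table(spectrum, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a fitted modular factorization model as text tables
#'
#' Writes `W.tsv` (node x module weights), `G.tsv` per component, a
#' `scores.tsv` (subject x component), and a `model.json` manifest with
#' configuration, objective traces and convergence flags.
#'
#' @param model an `mcf_model`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_model <- function(model, dir) {
  stopifnot(inherits(model, "mcf_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  comps <- model$components
  for (m in seq_along(comps)) {
    co <- comps[[m]]
    Wtab <- data.frame(node_id = co$node_labels, co$W,
                       check.names = FALSE)
    utils::write.table(Wtab, file.path(dir, sprintf("W_component%d.tsv", m)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(co$G, file.path(dir, sprintf("G_component%d.tsv", m)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  scores <- data.frame(subject_id = comps[[1]]$subject_ids,
                       vapply(comps, `[[`, numeric(length(comps[[1]]$scores)),
                              "scores"))
  names(scores) <- c("subject_id", paste0("component", seq_along(comps)))
  utils::write.table(scores, file.path(dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(K = model$K, M = model$M,
               config = model$config[setdiff(names(model$config), NULL)],
               total_variance = model$total_variance,
               adjusted_variance = as.list(model$adjusted),
               objective = vapply(comps, `[[`, numeric(1), "objective"),
               converged = vapply(comps, `[[`, logical(1), "converged"),
               objective_trace = lapply(comps, `[[`, "objective_trace"))
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
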