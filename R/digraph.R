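#' Build the map digraph specification for a given state
#'
#' Produces the visual coding of the map digraph: each construct becomes a
#' node named after the pole the person currently occupies (evaluated at
#' `state`), coloured by status (red = discrepant, green = congruent,
#' yellow = dilemmatic), and sized proportionally to |activation|. Each
#' nonzero weight becomes an edge whose *displayed* sign is re-expressed in
#' the poles the two nodes display:
#'
#'   `sign_hat[i, j] = sign(w[i, j] * p_i * p_j)`
#'
#' where the display polarity `p_k` is +1 if node k displays its right pole
#' and -1 if its left pole. A black edge (displayed sign > 0) reads "more of
#' my pole means more of your pole"; a red edge (displayed sign < 0) reads
#' "more of my pole means less of your pole". A node at activation 0
#' displays the pole opposite its ideal (matching [self_pole_label()]); if
#' the ideal is also at the midpoint the node keeps the canonical (right)
#' polarity and a combined "left vs right" label.
#'
#' @param state activation vector at the iteration to display.
#' @param model an [fcm_model()].
#' @param statuses aligned `construct_status` data frame.
#' @param grid the companion [repgrid()] (pole labels).
#' @param base_size,size_scale node size is
#'   `base_size + size_scale * |activation|` (defaults 10 and 20).
#' @param base_width,width_scale edge width is
#'   `base_width + width_scale * |weight|` (defaults 0.5 and 2.5).
#' @return An object of class `digraph_spec`: list of data frames `nodes`
#'   (id, label, status, color, activation, polarity, size) and `edges`
#'   (source, target, weight, displayed_sign, color, width).
#' @export
to_digraph <- function(state, model, statuses, grid,
                       base_size = 10, size_scale = 20,
                       base_width = 0.5, width_scale = 2.5) {
  stopifnot(inherits(model, "fcm_model"), inherits(grid, "repgrid"))
  n <- length(model$a0)
  state <- as.numeric(state)
  if (length(state) != n || nrow(statuses) != n ||
      nrow(grid$constructs) != n)
    stop("state, model, statuses and grid are not aligned", call. = FALSE)
  ideal <- statuses$ideal_activation
  polarity <- ifelse(state > 0, 1,
              ifelse(state < 0, -1,
              ifelse(ideal > 0, -1, ifelse(ideal < 0, 1, 1))))
  label <- character(n)
  for (i in seq_len(n)) {
    cns <- grid$constructs[i, ]
    label[i] <- if (state[i] == 0 && ideal[i] == 0)
      paste(cns$left_pole, "vs", cns$right_pole)
    else if (polarity[i] > 0) cns$right_pole else cns$left_pole
  }
  status_color <- c(discrepant = "red", congruent = "green",
                    dilemmatic = "yellow")
  nodes <- data.frame(
    id = seq_len(n),
    label = label,
    status = statuses$status,
    color = unname(status_color[statuses$status]),
    activation = state,
    polarity = polarity,
    size = base_size + size_scale * abs(state),
    stringsAsFactors = FALSE
  )
  nz <- which(model$W != 0, arr.ind = TRUE)
  nz <- nz[order(nz[, 1], nz[, 2]), , drop = FALSE]
  w <- model$W[nz]
  disp <- sign(w * polarity[nz[, 1]] * polarity[nz[, 2]])
  edges <- data.frame(
    source = as.integer(nz[, 1]),
    target = as.integer(nz[, 2]),
    weight = w,
    displayed_sign = disp,
    color = ifelse(disp > 0, "black", "red"),
    width = base_width + width_scale * abs(w),
    stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, edges = edges), class = "digraph_spec")
}

#' @export
print.digraph_spec <- function(x, ...) {
  cat(sprintf("Map digraph: %d node(s) (%s), %d edge(s) (%d direct, %d inverse)\n",
              nrow(x$nodes),
              paste(sprintf("%d %s", table(x$nodes$status),
                            names(table(x$nodes$status))), collapse = ", "),
              nrow(x$edges), sum(x$edges$displayed_sign > 0),
              sum(x$edges$displayed_sign < 0)))
  invisible(x)
}

#' Export a map digraph to DOT, GraphML or JSON
#'
#' DOT and GraphML are written through the igraph writers with node
#' attributes `label`, `color`, `size`, `status` and edge attributes
#' `color`, `width`, `sign`, `weight`. The JSON format mirrors the
#' `digraph_spec` object and round-trips losslessly through
#' [read_digraph_json()].
#'
#' @param spec a [to_digraph()] result.
#' @param format `"dot"`, `"graphml"` or `"json"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_graph <- function(spec, format = c("dot", "graphml", "json"), path) {
  format <- match.arg(format)
  stopifnot(inherits(spec, "digraph_spec"))
  if (format == "json") {
    jsonlite::write_json(list(nodes = spec$nodes, edges = spec$edges),
                         path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
    return(invisible(path))
  }
  g <- igraph::make_empty_graph(n = nrow(spec$nodes), directed = TRUE)
  igraph::V(g)$name <- as.character(spec$nodes$id)
  igraph::V(g)$label <- spec$nodes$label
  igraph::V(g)$color <- spec$nodes$color
  igraph::V(g)$size <- spec$nodes$size
  igraph::V(g)$status <- spec$nodes$status
  if (nrow(spec$edges)) {
    g <- igraph::add_edges(g, rbind(spec$edges$source, spec$edges$target))
    igraph::E(g)$color <- spec$edges$color
    igraph::E(g)$width <- spec$edges$width
    igraph::E(g)$sign <- spec$edges$displayed_sign
    igraph::E(g)$weight <- spec$edges$weight
  }
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' @rdname export_graph
#' @export
read_digraph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
  # JSON carries no integer/double distinction; restore the spec's types
  nodes$id <- as.integer(nodes$id)
  for (col in c("activation", "polarity", "size"))
    nodes[[col]] <- as.numeric(nodes[[col]])
  edges <- if (length(obj$edges)) {
    as.data.frame(obj$edges, stringsAsFactors = FALSE)
  } else {
    data.frame(source = integer(), target = integer(), weight = numeric(),
               displayed_sign = numeric(), color = character(),
               width = numeric(), stringsAsFactors = FALSE)
  }
  edges$source <- as.integer(edges$source)
  edges$target <- as.integer(edges$target)
  for (col in c("weight", "displayed_sign", "width"))
    edges[[col]] <- as.numeric(edges[[col]])
  structure(list(nodes = nodes, edges = edges), class = "digraph_spec")
}
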