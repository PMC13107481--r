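#' Build the X-maze track graph
#'
#' Constructs the track graph of the figure-X maze used throughout the
#' pipeline: two sample arms and two choice arms (each a 40-cm arm plus a
#' 10-cm reward zone ending at a reward port) joined by a 30-cm center arm,
#' 230 cm of track in total. The graph carries a 1D linearization layout in
#' which the five blocks (N-sample, S-sample, center, N-choice, S-choice) are
#' laid end to end with a 15-cm buffer between consecutive blocks; buffers are
#' never emitted as positions and never enter distance calculations. The
#' N-sample reward port sits at linearized position 0 and the S-sample reward
#' zone occupies 65-75 cm.
#'
#' @param arm_length arm length in cm between the junction and the reward
#'   zone (default 40).
#' @param reward_length reward-zone length in cm at the end of each arm
#'   (default 10).
#' @param center_length length in cm of the center arm joining the two
#'   junctions (default 30).
#' @param buffer buffer inserted between linearization blocks in cm
#'   (default 15).
#' @param bin_size position bin size in cm for the decoder state space
#'   (default 2).
#' @return an object of class \code{track_graph}: nodes (with 2D embedding at
#'   +/- 45 degrees), edges with lengths, the linear layout, the node distance
#'   matrix, and the on-track position bins.
#' @export
build_xmaze_graph <- function(arm_length = 40, reward_length = 10,
                              center_length = 30, buffer = 15, bin_size = 2) {
  if (arm_length <= 0 || reward_length <= 0 || center_length <= 0)
    stop("segment lengths must be positive")
  half <- arm_length + reward_length
  if (bin_size <= 0 || (2 * half + center_length) %% bin_size != 0)
    stop("inconsistent geometry: segments do not tile the track into whole bins")

  d <- half / sqrt(2)  # arm projection for the +/-45 degree embedding
  nodes <- data.frame(
    id = c("N_sample_port", "S_sample_port", "J_sample", "J_choice",
           "N_choice_port", "S_choice_port"),
    x = c(-d, -d, 0, center_length, center_length + d, center_length + d),
    y = c(d, -d, 0, 0, d, -d),
    stringsAsFactors = FALSE
  )
  # orientation from -> to defines the direction of increasing linear offset
  edges <- data.frame(
    id = c("N_sample", "S_sample", "center", "N_choice", "S_choice"),
    from = c("N_sample_port", "S_sample_port", "J_sample", "J_choice", "J_choice"),
    to = c("J_sample", "J_sample", "J_choice", "N_choice_port", "S_choice_port"),
    length = c(half, half, center_length, half, half),
    stringsAsFactors = FALSE
  )

  lin_start <- cumsum(c(0, head(edges$length, -1) + buffer))
  layout <- data.frame(
    edge = edges$id,
    lin_start = lin_start,
    lin_end = lin_start + edges$length,
    buffer_before = c(0, rep(buffer, nrow(edges) - 1)),
    stringsAsFactors = FALSE
  )

  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE, vertices = nodes)
  node_dist <- igraph::distances(g, weights = edges$length)

  tg <- structure(list(
    nodes = nodes, edges = edges, layout = layout,
    graph = g, node_dist = node_dist,
    total_length = sum(edges$length),
    arm_length = arm_length, reward_length = reward_length,
    center_length = center_length, buffer = buffer, bin_size = bin_size
  ), class = "track_graph")
  tg$bins <- track_bins(tg)
  tg
}

#' @export
print.track_graph <- function(x, ...) {
  cat(sprintf("track_graph: %d nodes, %d edges, %g cm of track (%d %g-cm bins)\n",
              nrow(x$nodes), nrow(x$edges), x$total_length,
              nrow(x$bins), x$bin_size))
  invisible(x)
}

#' On-track position bins
#'
#' Centers of the position bins tiling the on-track portion of the linear
#' layout (buffers excluded). These bins are the decoder's position state
#' space.
#'
#' @param graph a \code{track_graph}.
#' @param bin_size bin size in cm; defaults to the graph's.
#' @return data.frame with columns \code{bin}, \code{linear} (layout cm of the
#'   bin center), \code{segment}, \code{side}.
#' @export
track_bins <- function(graph, bin_size = graph$bin_size) {
  centers <- unlist(lapply(seq_len(nrow(graph$layout)), function(i) {
    seq(graph$layout$lin_start[i] + bin_size / 2,
        graph$layout$lin_end[i] - bin_size / 2, by = bin_size)
  }))
  seg <- segment_of(centers, graph)
  data.frame(bin = seq_along(centers), linear = centers,
             segment = seg$segment, side = seg$side,
             stringsAsFactors = FALSE)
}

# linear layout coordinate -> (edge index, offset from the edge's from-node)
# values inside buffers or outside the layout map to NA
linear_to_edge <- function(lin, graph) {
  lay <- graph$layout
  edge <- rep(NA_integer_, length(lin))
  offset <- rep(NA_real_, length(lin))
  for (i in seq_len(nrow(lay))) {
    inb <- !is.na(lin) & lin >= lay$lin_start[i] & lin <= lay$lin_end[i]
    edge[inb] <- i
    offset[inb] <- lin[inb] - lay$lin_start[i]
  }
  list(edge = edge, offset = offset)
}

#' Map a linearized position back to its 2D point on the track
#'
#' @param lin linearized position(s), layout cm.
#' @param graph a \code{track_graph}.
#' @return matrix with columns x, y (cm); rows NA for off-layout input.
#' @export
embed_linear <- function(lin, graph) {
  eo <- linear_to_edge(lin, graph)
  out <- matrix(NA_real_, length(lin), 2, dimnames = list(NULL, c("x", "y")))
  ok <- !is.na(eo$edge)
  if (any(ok)) {
    ed <- graph$edges[eo$edge[ok], ]
    p0 <- graph$nodes[match(ed$from, graph$nodes$id), c("x", "y")]
    p1 <- graph$nodes[match(ed$to, graph$nodes$id), c("x", "y")]
    f <- eo$offset[ok] / ed$length
    out[ok, 1] <- p0$x + f * (p1$x - p0$x)
    out[ok, 2] <- p0$y + f * (p1$y - p0$y)
  }
  out
}

#' Linearize 2D positions onto the track graph
#'
#' Projects each 2D point onto the nearest track edge and returns the
#' corresponding linear layout coordinate. Buffers are never produced. Points
#' farther than \code{snap_radius} from every edge return NA.
#'
#' @param x,y 2D coordinates in cm.
#' @param graph a \code{track_graph}.
#' @param snap_radius maximum projection distance in cm (default 20).
#' @return numeric vector of linearized positions (layout cm).
#' @export
linearize <- function(x, y, graph, snap_radius = 20) {
  n <- length(x)
  stopifnot(length(y) == n)
  best_d2 <- rep(Inf, n)
  best_lin <- rep(NA_real_, n)
  for (i in seq_len(nrow(graph$edges))) {
    ed <- graph$edges[i, ]
    p0 <- unlist(graph$nodes[match(ed$from, graph$nodes$id), c("x", "y")])
    p1 <- unlist(graph$nodes[match(ed$to, graph$nodes$id), c("x", "y")])
    vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
    L2 <- vx^2 + vy^2
    t <- pmin(1, pmax(0, ((x - p0[1]) * vx + (y - p0[2]) * vy) / L2))
    d2 <- (x - (p0[1] + t * vx))^2 + (y - (p0[2] + t * vy))^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_lin[upd] <- graph$layout$lin_start[i] + t[upd] * ed$length
  }
  best_lin[sqrt(best_d2) > snap_radius | is.na(x) | is.na(y)] <- NA_real_
  best_lin
}

#' Buffer-free distance along the track
#'
#' Shortest-path distance along the track graph between two linearized
#' positions. Buffers in the linear layout do not contribute: the distance is
#' measured along the physical track only.
#'
#' @param a,b linearized positions (layout cm); recycled to a common length.
#' @param graph a \code{track_graph}.
#' @return distance(s) in cm.
#' @export
track_distance <- function(a, b, graph) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  ea <- linear_to_edge(a, graph); eb <- linear_to_edge(b, graph)
  if (anyNA(ea$edge[!is.na(a)]) || anyNA(eb$edge[!is.na(b)]))
    stop("off-track position passed to track_distance")
  out <- rep(NA_real_, n)
  same <- !is.na(ea$edge) & !is.na(eb$edge) & ea$edge == eb$edge
  out[same] <- abs(ea$offset[same] - eb$offset[same])
  diff <- which(!is.na(ea$edge) & !is.na(eb$edge) & ea$edge != eb$edge)
  if (length(diff)) {
    D <- graph$node_dist
    nid <- graph$nodes$id
    fa <- match(graph$edges$from[ea$edge[diff]], nid)
    ta <- match(graph$edges$to[ea$edge[diff]], nid)
    fb <- match(graph$edges$from[eb$edge[diff]], nid)
    tb <- match(graph$edges$to[eb$edge[diff]], nid)
    sa <- ea$offset[diff]; la <- graph$edges$length[ea$edge[diff]]
    sb <- eb$offset[diff]; lb <- graph$edges$length[eb$edge[diff]]
    out[diff] <- pmin(
      sa + D[cbind(fa, fb)] + sb,
      sa + D[cbind(fa, tb)] + (lb - sb),
      (la - sa) + D[cbind(ta, fb)] + sb,
      (la - sa) + D[cbind(ta, tb)] + (lb - sb))
  }
  out
}

#' Task segment of a linearized position
#'
#' Assigns each on-track linearized position one of the five task segments:
#' sample reward, sample arm, center, choice arm, choice reward. A reward zone
#' is the track strictly within \code{reward_length} of its port, the port
#' itself included; a point exactly at the reward/arm boundary belongs to the
#' arm.
#'
#' @param lin linearized position(s), layout cm.
#' @param graph a \code{track_graph}.
#' @return data.frame with columns \code{segment} (factor-like character) and
#'   \code{side} ("N", "S" or "none").
#' @export
segment_of <- function(lin, graph) {
  eo <- linear_to_edge(lin, graph)
  seg <- rep(NA_character_, length(lin))
  side <- rep(NA_character_, length(lin))
  rl <- graph$reward_length
  len <- graph$edges$length
  for (i in seq_along(lin)) {
    e <- eo$edge[i]
    if (is.na(e)) next
    off <- eo$offset[i]
    nm <- graph$edges$id[e]
    if (nm == "center") {
      seg[i] <- "center"; side[i] <- "none"
    } else {
      # distance from the port: ports are the 'from' node of sample edges and
      # the 'to' node of choice edges
      dport <- if (grepl("sample", nm)) off else len[e] - off
      kind <- if (grepl("sample", nm)) "sample" else "choice"
      seg[i] <- if (dport < rl) paste0(kind, "_reward") else paste0(kind, "_arm")
      side[i] <- substr(nm, 1, 1)
    }
  }
  data.frame(segment = seg, side = side, stringsAsFactors = FALSE)
}

#' Segment names in track order
#' @export
segment_levels <- function()
  c("sample_reward", "sample_arm", "center", "choice_arm", "choice_reward")

# 1-cm grid of on-track cell centers used by the chance geometry
chance_grid <- function(graph) {
  lay <- graph$layout
  unlist(lapply(seq_len(nrow(lay)), function(i)
    seq(lay$lin_start[i] + 0.5, lay$lin_end[i] - 0.5, by = 1)))
}

#' Chance level of nonlocal decoding to a maze segment
#'
#' The chance probability that a nonlocally decoded position falls in a given
#' target segment, for an animal paused at a given position: the length of the
#' target segment lying at least \code{local_radius} cm (track distance) from
#' the animal, divided by the total track length at least that far away. In
#' segment mode the point-mode value is averaged over a 1-cm grid of animal
#' positions spanning the segment (both sides).
#'
#' @param mouse either a numeric linearized position (point mode) or a segment
#'   name from \code{segment_levels()} (segment mode).
#' @param target target segment name.
#' @param graph a \code{track_graph}.
#' @param local_radius local exclusion radius in cm (default 20).
#' @return probability in [0, 1].
#' @export
chance_level <- function(mouse, target, graph, local_radius = 20) {
  stopifnot(target %in% segment_levels())
  if (local_radius >= graph$total_length)
    stop("local_radius covers the whole maze: chance denominator is zero")
  grid <- chance_grid(graph)
  gseg <- segment_of(grid, graph)$segment
  point_chance <- function(pos) {
    d <- track_distance(rep(pos, length(grid)), grid, graph)
    far <- d >= local_radius
    denom <- sum(far)
    if (denom == 0) stop("local_radius covers the whole maze")
    sum(far & gseg == target) / denom
  }
  if (is.character(mouse)) {
    stopifnot(mouse %in% segment_levels())
    at <- grid[gseg == mouse]
    mean(vapply(at, point_chance, 0))
  } else {
    point_chance(mouse)
  }
}

#' Nonlocal chance denominator
#'
#' Total on-track length lying at least \code{local_radius} cm of track
#' distance away from an animal at \code{pos} - the denominator of the chance
#' geometry.
#'
#' @inheritParams chance_level
#' @param pos linearized animal position (layout cm).
#' @return length in cm.
#' @export
nonlocal_denominator <- function(pos, graph, local_radius = 20) {
  grid <- chance_grid(graph)
  d <- track_distance(rep(pos, length(grid)), grid, graph)
  sum(d >= local_radius)  # 1-cm cells
}

# pairwise track distances between decoder bin centers (B x B, cm)
bin_distance_matrix <- function(graph) {
  ctr <- graph$bins$linear
  B <- length(ctr)
  i <- rep(seq_len(B), B)
  j <- rep(seq_len(B), each = B)
  matrix(track_distance(ctr[i], ctr[j], graph), B, B)
}

#' Serialize / restore a track graph as JSON
#' @param graph a \code{track_graph}.
#' @param path file path.
#' @export
track_to_json <- function(graph, path) {
  jsonlite::write_json(list(
    nodes = graph$nodes, edges = graph$edges, layout = graph$layout,
    params = list(arm_length = graph$arm_length,
                  reward_length = graph$reward_length,
                  center_length = graph$center_length,
                  buffer = graph$buffer, bin_size = graph$bin_size)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname track_to_json
#' @export
track_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)$params
  build_xmaze_graph(p$arm_length, p$reward_length, p$center_length,
                    p$buffer, p$bin_size)
}
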