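#' Parameters for NIOSH 7400 / AIA fibre counting
#'
#' Countable fibres are longer than `min_length` along their elongation axis,
#' narrower than `max_width`, have aspect ratio above `min_aspect_ratio`, and
#' carry no attached particle larger than `blob_diameter_limit`; crossed
#' fibres are counted individually, branched fibres as one fibre, and
#' entangled objects are not counted at all. Entanglement is operationalised
#' topologically: objects whose skeleton has more than
#' `entangle_junction_limit` junctions or more than `entangle_loop_limit`
#' independent loops are skipped. `collinearity_tolerance` controls when two
#' branches meeting at a junction are treated as one fibre passing through
#' (their directions within that many degrees of opposite).
#'
#' @param min_length Minimum fibre length, um (strict `>`).
#' @param max_width Maximum fibre width, um (strict `<`).
#' @param min_aspect_ratio Minimum length/width ratio (strict `>`).
#' @param blob_diameter_limit Maximum attached-particle diameter, um.
#' @param entangle_junction_limit,entangle_loop_limit Topological limits
#'   beyond which an object counts as entangled.
#' @param collinearity_tolerance Degrees.
#' @return An object of class `niosh_params`.
#' @export
niosh_params <- function(min_length = 5, max_width = 3, min_aspect_ratio = 3,
                         blob_diameter_limit = 3,
                         entangle_junction_limit = 3, entangle_loop_limit = 1,
                         collinearity_tolerance = 30) {
  for (nm in c("min_length", "max_width", "min_aspect_ratio",
               "blob_diameter_limit", "collinearity_tolerance")) {
    check_scalar_number(get(nm), nm, min = 0, strict_min = TRUE)
  }
  check_scalar_number(entangle_junction_limit, "entangle_junction_limit", min = 0)
  check_scalar_number(entangle_loop_limit, "entangle_loop_limit", min = 0)
  structure(
    list(
      min_length = min_length, max_width = max_width,
      min_aspect_ratio = min_aspect_ratio,
      blob_diameter_limit = blob_diameter_limit,
      entangle_junction_limit = entangle_junction_limit,
      entangle_loop_limit = entangle_loop_limit,
      collinearity_tolerance = collinearity_tolerance
    ),
    class = "niosh_params"
  )
}

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Zhang-Suen thinning of a logical matrix to a 1-px-wide skeleton.
zhang_suen <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  # neighbour order P2..P9 clockwise starting north (row - 1)
  offs <- list(
    c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
    c(1, 0), c(1, -1), c(0, -1), c(-1, -1)
  )
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- lapply(offs, function(o) shift_mat(m, -o[1], -o[2]))
      B <- Reduce(`+`, nb)
      A <- Reduce(`+`, lapply(1:8, function(i) {
        (nb[[i]] == 0L) & (nb[[if (i == 8) 1 else i + 1]] == 1L)
      }))
      P2 <- nb[[1]]; P4 <- nb[[3]]; P6 <- nb[[5]]; P8 <- nb[[7]]
      if (step == 1) {
        cond <- P2 * P4 * P6 == 0L & P4 * P6 * P8 == 0L
      } else {
        cond <- P2 * P4 * P8 == 0L & P2 * P6 * P8 == 0L
      }
      del <- m == 1L & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# Adjacency of skeleton pixels: 8-connectivity with redundant diagonal edges
# removed (a diagonal edge is dropped when the two pixels share an orthogonal
# skeleton neighbour), so corner turns do not create spurious 3-cycles.
skeleton_adjacency <- function(skel) {
  nr <- nrow(skel)
  idx <- which(skel)
  edges <- mask_adjacency(skel, 8)
  if (nrow(edges) == 0) return(list(idx = idx, edges = edges))
  r1 <- ((edges[, 1] - 1L) %% nr) + 1L
  c1 <- ((edges[, 1] - 1L) %/% nr) + 1L
  r2 <- ((edges[, 2] - 1L) %% nr) + 1L
  c2 <- ((edges[, 2] - 1L) %/% nr) + 1L
  diag_edge <- r1 != r2 & c1 != c2
  redundant <- diag_edge &
    (skel[cbind(r1, c2)] | skel[cbind(r2, c1)])
  list(idx = idx, edges = edges[!redundant, , drop = FALSE])
}

#' Skeletonize a single object into a topological graph
#'
#' Thins the object to a one-pixel-wide medial skeleton (Zhang-Suen), then
#' builds a graph whose nodes are skeleton endpoints (degree 1) and junction
#' clusters (adjacent pixels of degree >= 3 merged), and whose edges are the
#' pixel chains between them. Each edge carries its geodesic path length
#' (sum of pixel steps, in um) and the local widths sampled along it from
#' the Euclidean distance transform of the object
#' (`width = (2 d - 1) * pixel_size`, exact for odd pixel widths). A closed
#' ring with no junctions is represented as one self-loop edge.
#'
#' @param mask Logical matrix (one connected object) or a [binary_mask()].
#' @param pixel_size Micrometres per pixel (taken from the mask if a
#'   `binary_mask`).
#' @return An object of class `skeleton_graph`: tibbles `nodes` (`id`,
#'   `type`, `x`, `y`), `edges` (`from`, `to`, `path_length`,
#'   `mean_local_width`, list-columns `path_x`, `path_y`, `widths`), and
#'   `n_loops`.
#' @export
skeletonize_object <- function(mask, pixel_size = NULL) {
  if (inherits(mask, "binary_mask")) {
    pixel_size <- mask$pixel_size
    mask <- mask$pixels
  }
  if (is.null(pixel_size)) abort("`pixel_size` is required.")
  ps <- pixel_size
  if (!any(mask)) {
    return(structure(
      list(
        nodes = tibble(id = integer(), type = character(),
                       x = numeric(), y = numeric()),
        edges = empty_skeleton_edges(),
        n_loops = 0L, pixel_size = ps
      ),
      class = "skeleton_graph"
    ))
  }
  # pad so thinning and distmap see a background frame
  pad <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  skel <- zhang_suen(pad)
  dmap <- EBImage::imageData(EBImage::distmap(
    EBImage::Image(matrix(as.numeric(pad), nrow(pad), ncol(pad)))
  ))
  adj <- skeleton_adjacency(skel)
  idx <- adj$idx
  nr <- nrow(pad)
  coord_x <- function(i) (((i - 1L) %/% nr) + 1L - 1 - 0.5) * ps  # unpad
  coord_y <- function(i) (((i - 1L) %% nr) + 1L - 1 - 0.5) * ps
  vid <- match(idx, idx)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(adj$edges)) {
    g <- igraph::add_edges(g, as.vector(t(matrix(
      match(as.vector(adj$edges), idx), ncol = 2
    ))))
  }
  deg <- igraph::degree(g)
  junction <- deg >= 3
  endpoint <- deg <= 1

  # junction clusters
  jcluster <- rep(NA_integer_, length(idx))
  if (any(junction)) {
    sub <- igraph::induced_subgraph(g, which(junction))
    memb <- igraph::components(sub)$membership
    jcluster[which(junction)] <- memb
  }
  n_jc <- if (any(junction)) max(jcluster, na.rm = TRUE) else 0L

  nodes <- list()
  node_of_pixel <- rep(NA_integer_, length(idx))
  nid <- 0L
  if (n_jc > 0) {
    for (k in seq_len(n_jc)) {
      nid <- nid + 1L
      pix <- which(!is.na(jcluster) & jcluster == k)
      node_of_pixel[pix] <- nid
      nodes[[nid]] <- tibble(
        id = nid, type = "junction",
        x = mean(coord_x(idx[pix])), y = mean(coord_y(idx[pix]))
      )
    }
  }
  for (p in which(endpoint)) {
    nid <- nid + 1L
    node_of_pixel[p] <- nid
    nodes[[nid]] <- tibble(
      id = nid, type = "endpoint",
      x = coord_x(idx[p]), y = coord_y(idx[p])
    )
  }
  nodes <- if (length(nodes)) bind_rows(nodes) else
    tibble(id = integer(), type = character(), x = numeric(), y = numeric())

  widths_at <- function(pix) (2 * dmap[idx[pix]] - 1) * ps
  # geodesic length of a pixel chain: chord sum over a coarsened polyline
  # (about 1 um spacing), since the raw staircase overestimates oblique runs
  step_len <- function(xs, ys) {
    n <- length(xs)
    if (n < 2) return(0)
    stride <- max(2, round(1 / ps))
    keep <- unique(c(seq(1, n, by = stride), n))
    sum(sqrt(diff(xs[keep])^2 + diff(ys[keep])^2))
  }
  # thinning erodes fibre tips: extend a free path end along its local
  # direction until the object boundary, and return the added length
  inside_mask <- function(x, y) {
    r <- floor(y / ps) + 2L  # back to padded row/col
    c <- floor(x / ps) + 2L
    r >= 1 && r <= nrow(pad) && c >= 1 && c <= ncol(pad) && pad[r, c]
  }
  tip_extension <- function(xs, ys) {
    n <- length(xs)
    if (n < 2) return(0)
    k <- max(1, n - max(3, ceiling(1 / ps)))
    ux <- xs[n] - xs[k]
    uy <- ys[n] - ys[k]
    nrm <- sqrt(ux^2 + uy^2)
    if (nrm == 0) return(0)
    ux <- ux / nrm
    uy <- uy / nrm
    step <- ps / 4
    ext <- 0
    while (ext < 10 && inside_mask(xs[n] + (ext + step) * ux,
                                   ys[n] + (ext + step) * uy)) {
      ext <- ext + step
    }
    ext
  }
  neighbours <- lapply(seq_along(idx), function(v) {
    as.integer(igraph::neighbors(g, v))
  })

  edges <- list()
  node_type <- function(id) nodes$type[match(id, nodes$id)]
  add_edge <- function(from, to, pix_chain, closed = FALSE) {
    xs <- coord_x(idx[pix_chain])
    ys <- coord_y(idx[pix_chain])
    w <- widths_at(pix_chain)
    ext <- 0
    if (!closed) {
      if (identical(node_type(from), "endpoint")) {
        ext <- ext + tip_extension(rev(xs), rev(ys))
      }
      if (to != from && identical(node_type(to), "endpoint")) {
        ext <- ext + tip_extension(xs, ys)
      }
    }
    edges[[length(edges) + 1L]] <<- tibble(
      from = from, to = to,
      path_length = max(step_len(xs, ys) + ext, ps),
      mean_local_width = mean(w),
      path_x = list(xs), path_y = list(ys), widths = list(w)
    )
  }

  chain_pix <- which(!junction)
  if (length(chain_pix)) {
    subc <- igraph::induced_subgraph(g, chain_pix)
    membc <- igraph::components(subc)$membership
    for (k in seq_len(max(membc))) {
      comp <- chain_pix[membc == k]
      # order pixels along the path
      sub2 <- igraph::induced_subgraph(g, comp)
      d2 <- igraph::degree(sub2)
      if (all(d2 == 2)) {
        # pure ring: one self-loop node at an arbitrary pixel
        ord <- comp[as.integer(igraph::dfs(sub2, root = 1)$order)]
        nid <- nid + 1L
        nodes <- bind_rows(nodes, tibble(
          id = nid, type = "endpoint",
          x = coord_x(idx[ord[1]]), y = coord_y(idx[ord[1]])
        ))
        add_edge(nid, nid, c(ord, ord[1]), closed = TRUE)
        next
      }
      ends <- which(d2 <= 1)
      ord <- comp[as.integer(igraph::dfs(sub2, root = ends[1])$order)]
      # attachments to junction clusters at each terminal
      term_nodes <- lapply(c(ord[1], ord[length(ord)]), function(p) {
        nb <- neighbours[[p]]
        jn <- unique(node_of_pixel[nb[junction[nb]]])
        jn[!is.na(jn)]
      })
      from <- if (length(term_nodes[[1]])) term_nodes[[1]][1] else
        node_of_pixel[ord[1]]
      to <- if (length(term_nodes[[2]])) term_nodes[[2]][1] else
        node_of_pixel[ord[length(ord)]]
      # extend the chain into the junction pixel for length continuity
      chain <- ord
      if (length(term_nodes[[1]])) {
        nb <- neighbours[[ord[1]]]
        jpix <- nb[junction[nb] & node_of_pixel[nb] == from][1]
        chain <- c(jpix, chain)
      }
      if (length(term_nodes[[2]])) {
        nb <- neighbours[[ord[length(ord)]]]
        jpix <- nb[junction[nb] & node_of_pixel[nb] == to][1]
        chain <- c(chain, jpix)
      }
      add_edge(from, to, chain)
    }
  }
  # direct junction-junction adjacencies between different clusters
  if (n_jc > 1 && nrow(adj$edges)) {
    e1 <- match(adj$edges[, 1], idx)
    e2 <- match(adj$edges[, 2], idx)
    both_j <- junction[e1] & junction[e2] &
      node_of_pixel[e1] != node_of_pixel[e2]
    if (any(both_j)) {
      seen <- character()
      for (i in which(both_j)) {
        key <- paste(sort(c(node_of_pixel[e1[i]], node_of_pixel[e2[i]])),
                     collapse = "-")
        if (key %in% seen) next
        seen <- c(seen, key)
        add_edge(node_of_pixel[e1[i]], node_of_pixel[e2[i]], c(e1[i], e2[i]))
      }
    }
  }
  edges <- if (length(edges)) bind_rows(edges) else empty_skeleton_edges()

  # isolated skeleton pixels (degree 0): dot-like objects
  if (any(deg == 0)) {
    for (p in which(deg == 0)) {
      nid <- nid + 1L
      nodes <- bind_rows(nodes, tibble(
        id = nid, type = "endpoint",
        x = coord_x(idx[p]), y = coord_y(idx[p])
      ))
      edges <- bind_rows(edges, tibble(
        from = nid, to = nid, path_length = ps,
        mean_local_width = (2 * dmap[idx[p]] - 1) * ps,
        path_x = list(coord_x(idx[p])), path_y = list(coord_y(idx[p])),
        widths = list((2 * dmap[idx[p]] - 1) * ps)
      ))
    }
  }

  merged <- merge_close_junctions(nodes, edges, ps)
  nodes <- merged$nodes
  edges <- merged$edges
  # relabel node ids consecutively (junction merging leaves gaps)
  if (nrow(nodes)) {
    remap <- setNames(seq_len(nrow(nodes)), nodes$id)
    nodes$id <- seq_len(nrow(nodes))
    if (nrow(edges)) {
      edges$from <- unname(remap[as.character(edges$from)])
      edges$to <- unname(remap[as.character(edges$to)])
    }
  }

  n_nodes <- nrow(nodes)
  n_edges <- nrow(edges)
  n_comp <- if (n_edges == 0) n_nodes else {
    tg <- igraph::graph_from_edgelist(
      as.matrix(edges[, c("from", "to")]), directed = FALSE
    )
    tg <- igraph::add_vertices(tg, max(0L, n_nodes - igraph::vcount(tg)))
    igraph::components(tg)$no
  }
  structure(
    list(
      nodes = nodes, edges = edges,
      n_loops = as.integer(max(0, n_edges - n_nodes + n_comp)),
      pixel_size = ps
    ),
    class = "skeleton_graph"
  )
}

# Thinning splits an oblique crossing into two nearby junctions joined by a
# short bridge. Contract junction-junction bridges not longer than
# max(3 px, 2.5 x local width) into one junction, spreading the bridge
# length over the incident edges so total skeleton length is conserved.
merge_close_junctions <- function(nodes, edges, ps) {
  repeat {
    if (nrow(edges) == 0) break
    jids <- nodes$id[nodes$type == "junction"]
    cand <- which(
      edges$from %in% jids & edges$to %in% jids & edges$from != edges$to &
        edges$path_length <= pmax(3 * ps, 2.5 * edges$mean_local_width)
    )
    if (length(cand) == 0) break
    e <- cand[which.min(edges$path_length[cand])]
    a <- edges$from[e]
    b <- edges$to[e]
    bridge_len <- edges$path_length[e]
    ia <- match(a, nodes$id)
    ib <- match(b, nodes$id)
    nodes$x[ia] <- (nodes$x[ia] + nodes$x[ib]) / 2
    nodes$y[ia] <- (nodes$y[ia] + nodes$y[ib]) / 2
    nodes <- nodes[-ib, ]
    edges <- edges[-e, ]
    edges$from[edges$from == b] <- a
    edges$to[edges$to == b] <- a
    inc <- which(edges$from == a | edges$to == a)
    if (length(inc)) {
      edges$path_length[inc] <- edges$path_length[inc] +
        bridge_len / length(inc)
    }
  }
  list(nodes = nodes, edges = edges)
}

empty_skeleton_edges <- function() {
  tibble(
    from = integer(), to = integer(), path_length = numeric(),
    mean_local_width = numeric(), path_x = list(), path_y = list(),
    widths = list()
  )
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf(
    "<skeleton_graph> %d endpoints, %d junctions, %d edges, %d loop(s)\n",
    sum(x$nodes$type == "endpoint"), sum(x$nodes$type == "junction"),
    nrow(x$edges), x$n_loops
  ))
  invisible(x)
}

# Direction (radians) in which edge e leaves node `node`, measured from the
# node along the first ~1.5 um of the path.
edge_direction <- function(sg, e, node) {
  xs <- sg$edges$path_x[[e]]
  ys <- sg$edges$path_y[[e]]
  if (sg$edges$to[e] == node && sg$edges$from[e] != node) {
    xs <- rev(xs)
    ys <- rev(ys)
  }
  lookahead <- max(3, ceiling(1.5 / sg$pixel_size))
  k <- min(length(xs), lookahead + 1)
  if (k < 2) return(0)
  atan2(ys[k] - ys[1], xs[k] - xs[1])
}

angdev_from_opposite <- function(a, b) {
  d <- abs((a - b) %% (2 * pi))
  abs(180 - d * 180 / pi) %% 360
}

new_candidate <- function(parent_object_id, edges_idx, sg, topology) {
  len <- sum(sg$edges$path_length[edges_idx])
  w_all <- unlist(sg$edges$widths[edges_idx])
  tibble(
    parent_object_id = parent_object_id,
    path_length = len,
    mean_width = mean(w_all),
    max_attached_blob_diameter = blob_diameter(w_all),
    topology = topology
  )
}

# Attached-particle (blob) diameter along a candidate path: largest local
# width at positions where the local width exceeds twice the path's median
# width; 0 when the width profile is uniform.
blob_diameter <- function(widths) {
  med <- median(widths)
  fat <- widths > 2 * med
  if (!any(fat)) 0 else max(widths[fat])
}

longest_endpoint_geodesic <- function(sg) {
  ep <- sg$nodes$id[sg$nodes$type == "endpoint"]
  tg <- igraph::graph_from_edgelist(
    as.matrix(sg$edges[, c("from", "to")]), directed = FALSE
  )
  tg <- igraph::add_vertices(tg, max(0L, nrow(sg$nodes) - igraph::vcount(tg)))
  igraph::E(tg)$weight <- sg$edges$path_length
  if (length(ep) < 2) return(seq_len(nrow(sg$edges)))
  d <- igraph::distances(tg, v = ep, to = ep)
  d[!is.finite(d)] <- -1
  best <- which(d == max(d), arr.ind = TRUE)[1, ]
  sp <- igraph::shortest_paths(
    tg, from = ep[best[1]], to = ep[best[2]], output = "epath"
  )
  as.integer(sp$epath[[1]])
}

#' Classify the topology of a skeletonized object
#'
#' Applies the crossed / branched / entangled counting rules to a skeleton
#' graph: a junction- and loop-free skeleton is one simple fibre; a single
#' four-way junction whose branches pair up collinearly is a crossing and
#' yields two fibre candidates (crossed fibres are counted individually); a
#' single three-way junction is a branched fibre and yields one candidate
#' spanning the longest endpoint-to-endpoint geodesic (branched fibres count
#' once); objects with more junctions or loops than the entanglement limits
#' yield no candidates (entangled fibres are not counted). Remaining cases
#' are decomposed greedily by collinear pairing at each junction, absorbing
#' unpaired stubs shorter than `min_length`.
#'
#' @param sg A [skeletonize_object()] result.
#' @param params A [niosh_params()].
#' @param object_id Identifier copied onto the candidates.
#' @return A list: `topology` (`"simple"`, `"crossed"`, `"branched"`,
#'   `"entangled"` or `"empty"`), `candidates` (tibble:
#'   `parent_object_id`, `path_length`, `mean_width`,
#'   `max_attached_blob_diameter`, `topology`), and `n_absorbed`.
#' @export
classify_topology <- function(sg, params = niosh_params(), object_id = 1L) {
  stopifnot(inherits(sg, "skeleton_graph"))
  n_junc <- sum(sg$nodes$type == "junction")
  no_cand <- tibble(
    parent_object_id = integer(), path_length = numeric(),
    mean_width = numeric(), max_attached_blob_diameter = numeric(),
    topology = character()
  )
  if (nrow(sg$edges) == 0) {
    return(list(topology = "empty", candidates = no_cand, n_absorbed = 0L))
  }
  if (n_junc > params$entangle_junction_limit ||
      sg$n_loops > params$entangle_loop_limit) {
    return(list(topology = "entangled", candidates = no_cand, n_absorbed = 0L))
  }
  if (n_junc == 0) {
    # simple fibre (single chain or closed ring)
    return(list(
      topology = "simple",
      candidates = new_candidate(object_id, seq_len(nrow(sg$edges)), sg,
                                 "simple"),
      n_absorbed = 0L
    ))
  }
  if (n_junc == 1 && sg$n_loops == 0) {
    jid <- sg$nodes$id[sg$nodes$type == "junction"]
    inc <- which(sg$edges$from == jid | sg$edges$to == jid)
    degree <- length(inc) + sum(sg$edges$from[inc] == sg$edges$to[inc])
    if (degree == 4) {
      dirs <- vapply(inc, function(e) edge_direction(sg, e, jid), numeric(1))
      pairings <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
      devs <- vapply(pairings, function(p) {
        max(angdev_from_opposite(dirs[p[1]], dirs[p[2]]),
            angdev_from_opposite(dirs[p[3]], dirs[p[4]]))
      }, numeric(1))
      best <- which.min(devs)
      if (devs[best] <= params$collinearity_tolerance) {
        p <- pairings[[best]]
        return(list(
          topology = "crossed",
          candidates = bind_rows(
            new_candidate(object_id, inc[p[1:2]], sg, "crossed_member"),
            new_candidate(object_id, inc[p[3:4]], sg, "crossed_member")
          ),
          n_absorbed = 0L
        ))
      }
      # no collinear pairing: treat as branched
      return(list(
        topology = "branched",
        candidates = new_candidate(object_id, longest_endpoint_geodesic(sg),
                                   sg, "branched"),
        n_absorbed = 0L
      ))
    }
    if (degree == 3) {
      return(list(
        topology = "branched",
        candidates = new_candidate(object_id, longest_endpoint_geodesic(sg),
                                   sg, "branched"),
        n_absorbed = 0L
      ))
    }
  }
  greedy_decompose(sg, params, object_id)
}

# General case (2-3 junctions, or odd single-junction degrees): pair incident
# edge-ends at each junction by best collinearity, chain paired edges into
# candidates, absorb unpaired stubs shorter than min_length.
greedy_decompose <- function(sg, params, object_id) {
  ne <- nrow(sg$edges)
  # edge-end bookkeeping: partner[2e-1] pairs with end (e, from-side)
  partner <- rep(NA_integer_, 2 * ne)
  end_id <- function(e, side) 2L * e - 2L + side  # side 1 = from, 2 = to
  for (jid in sg$nodes$id[sg$nodes$type == "junction"]) {
    ends <- integer()
    for (e in seq_len(ne)) {
      if (sg$edges$from[e] == jid) ends <- c(ends, end_id(e, 1L))
      if (sg$edges$to[e] == jid) ends <- c(ends, end_id(e, 2L))
    }
    if (length(ends) < 2) next
    dirs <- vapply(ends, function(id) {
      edge_direction(sg, ((id - 1L) %/% 2L) + 1L, jid)
    }, numeric(1))
    pairs <- utils::combn(seq_along(ends), 2)
    devs <- apply(pairs, 2, function(p) {
      angdev_from_opposite(dirs[p[1]], dirs[p[2]])
    })
    ord <- order(devs)
    used <- logical(length(ends))
    for (k in ord) {
      if (devs[k] > params$collinearity_tolerance) break
      p <- pairs[, k]
      # do not pair two ends of the same edge (tight loop)
      if (((ends[p[1]] - 1L) %/% 2L) == ((ends[p[2]] - 1L) %/% 2L)) next
      if (used[p[1]] || used[p[2]]) next
      used[p[1]] <- used[p[2]] <- TRUE
      partner[ends[p[1]]] <- ends[p[2]]
      partner[ends[p[2]]] <- ends[p[1]]
    }
  }
  # walk chains of edges connected through paired ends
  visited <- logical(ne)
  cands <- list()
  n_absorbed <- 0L
  for (e0 in seq_len(ne)) {
    if (visited[e0]) next
    chain <- e0
    visited[e0] <- TRUE
    open_junction_end <- FALSE
    for (side0 in 1:2) {
      id <- end_id(e0, side0)
      repeat {
        nxt <- partner[id]
        if (is.na(nxt)) {
          e <- ((id - 1L) %/% 2L) + 1L
          side <- ((id - 1L) %% 2L) + 1L
          node <- if (side == 1) sg$edges$from[e] else sg$edges$to[e]
          if (sg$nodes$type[match(node, sg$nodes$id)] == "junction") {
            open_junction_end <- TRUE
          }
          break
        }
        e_next <- ((nxt - 1L) %/% 2L) + 1L
        if (visited[e_next]) break
        visited[e_next] <- TRUE
        chain <- c(chain, e_next)
        # continue from the far end of e_next
        id <- if (((nxt - 1L) %% 2L) + 1L == 1L) end_id(e_next, 2L) else
          end_id(e_next, 1L)
      }
    }
    len <- sum(sg$edges$path_length[chain])
    if (length(chain) == 1 && open_junction_end && len < params$min_length) {
      n_absorbed <- n_absorbed + 1L
      next
    }
    cands[[length(cands) + 1L]] <- new_candidate(
      object_id, chain, sg,
      if (length(chain) > 1) "crossed_member" else "branched"
    )
  }
  list(
    topology = "crossed",
    candidates = if (length(cands)) bind_rows(cands) else tibble(
      parent_object_id = integer(), path_length = numeric(),
      mean_width = numeric(), max_attached_blob_diameter = numeric(),
      topology = character()
    ),
    n_absorbed = n_absorbed
  )
}

#' Apply the geometric acceptance rules to fibre candidates
#'
#' A candidate is accepted as a countable fibre iff its skeleton path length
#' strictly exceeds `min_length`, its mean width is strictly below
#' `max_width`, its length/width ratio strictly exceeds `min_aspect_ratio`,
#' and its largest attached particle does not exceed `blob_diameter_limit`.
#' Rejections are tallied by the first failing rule.
#'
#' @param candidates Candidate tibble from [classify_topology()].
#' @param params A [niosh_params()].
#' @return A list: `accepted` (tibble of accepted candidates) and `rejected`
#'   (named integer vector: `too_short`, `too_wide`, `low_ar`, `blob`).
#' @export
apply_geometric_rules <- function(candidates, params = niosh_params()) {
  reasons <- c("too_short", "too_wide", "low_ar", "blob")
  rejected <- setNames(integer(4), reasons)
  if (nrow(candidates) == 0) {
    return(list(accepted = candidates, rejected = rejected))
  }
  reason <- dplyr::case_when(
    candidates$path_length <= params$min_length ~ "too_short",
    candidates$mean_width >= params$max_width ~ "too_wide",
    candidates$path_length / candidates$mean_width <=
      params$min_aspect_ratio ~ "low_ar",
    candidates$max_attached_blob_diameter > params$blob_diameter_limit ~ "blob",
    TRUE ~ "accepted"
  )
  for (r in reasons) rejected[r] <- sum(reason == r)
  list(accepted = candidates[reason == "accepted", ], rejected = rejected)
}

#' Count fibres in a labeled image under NIOSH 7400 rules
#'
#' Runs skeletonization, topology classification and the geometric
#' acceptance rules over every labeled object and aggregates the result:
#' number of countable fibres, inspected area, fibre density, accepted fibre
#' lengths and a tally of rejections by reason.
#'
#' @param labels A [label_objects()] result.
#' @param params A [niosh_params()].
#' @return An object of class `counting_result`: `n_images`,
#'   `inspected_area_mm2`, `n_fibres`, `fibres_per_mm2`, `fibre_lengths`,
#'   `rejected` (named vector incl. `entangled`), `n_candidates`,
#'   `n_absorbed` and a `fibres` tibble (`object_id`, `length_um`,
#'   `width_um`, `topology`).
#' @export
count_fibres <- function(labels, params = niosh_params()) {
  stopifnot(inherits(labels, "label_map"))
  ps <- labels$pixel_size
  area_mm2 <- nrow(labels$pixels) * ncol(labels$pixels) * ps^2 / 1e6
  rejected <- setNames(
    integer(5), c("too_short", "too_wide", "low_ar", "blob", "entangled")
  )
  fibres <- list()
  n_candidates <- 0L
  n_absorbed <- 0L
  lab <- labels$pixels
  nr <- nrow(lab)
  idx_all <- which(lab > 0L)
  by_obj <- split(idx_all, lab[idx_all])
  for (i in seq_len(labels$n_objects)) {
    px <- by_obj[[as.character(i)]]
    rows <- ((px - 1L) %% nr) + 1L
    cols <- ((px - 1L) %/% nr) + 1L
    sub <- matrix(FALSE, diff(range(rows)) + 1L, diff(range(cols)) + 1L)
    sub[cbind(rows - min(rows) + 1L, cols - min(cols) + 1L)] <- TRUE
    sg <- skeletonize_object(sub, ps)
    cl <- classify_topology(sg, params, object_id = i)
    if (cl$topology == "entangled") {
      rejected["entangled"] <- rejected["entangled"] + 1L
      next
    }
    n_candidates <- n_candidates + nrow(cl$candidates)
    n_absorbed <- n_absorbed + cl$n_absorbed
    rl <- apply_geometric_rules(cl$candidates, params)
    rejected[names(rl$rejected)] <- rejected[names(rl$rejected)] + rl$rejected
    if (nrow(rl$accepted)) {
      fibres[[length(fibres) + 1L]] <- tibble(
        object_id = rl$accepted$parent_object_id,
        length_um = rl$accepted$path_length,
        width_um = rl$accepted$mean_width,
        topology = rl$accepted$topology
      )
    }
  }
  fibres <- if (length(fibres)) bind_rows(fibres) else tibble(
    object_id = integer(), length_um = numeric(), width_um = numeric(),
    topology = character()
  )
  structure(
    list(
      n_images = 1L,
      inspected_area_mm2 = area_mm2,
      n_fibres = nrow(fibres),
      fibres_per_mm2 = nrow(fibres) / area_mm2,
      fibre_lengths = fibres$length_um,
      rejected = rejected,
      n_candidates = n_candidates,
      n_absorbed = n_absorbed,
      fibres = fibres
    ),
    class = "counting_result"
  )
}

#' @export
print.counting_result <- function(x, ...) {
  cat(sprintf(
    "<counting_result> %d fibres in %.3g mm^2 (%.0f fibres/mm^2); rejected: %s\n",
    x$n_fibres, x$inspected_area_mm2, x$fibres_per_mm2,
    paste(names(x$rejected), x$rejected, sep = "=", collapse = ", ")
  ))
  invisible(x)
}

#' Length histogram of counted fibres
#'
#' Bins accepted fibre lengths into fixed-width classes starting at the
#' minimum countable length (default 3-um classes from 5 um: 5-8, 8-11,
#' ...), normalised to fibres per mm^2, with cumulative percentages.
#'
#' @param result A [count_fibres()] result.
#' @param bin_width Class width in um.
#' @param start First class lower edge in um.
#' @return A `class_histogram` tibble (`class`, `count`, `per_mm2`,
#'   `cumulative_pct`).
#' @export
fibre_length_histogram <- function(result, bin_width = 3, start = 5) {
  stopifnot(inherits(result, "counting_result"))
  check_scalar_number(bin_width, "bin_width", min = 0, strict_min = TRUE)
  lengths <- result$fibre_lengths
  if (length(lengths) && min(lengths) < start) {
    warn("fibre lengths below `start` dropped from the histogram.")
    lengths <- lengths[lengths >= start]
  }
  n_bins <- max(1L, floor((max(lengths, start) - start) / bin_width) + 1L)
  edges <- start + bin_width * (0:n_bins)
  counts <- as.integer(tabulate(
    findInterval(lengths, edges, rightmost.closed = FALSE),
    nbins = n_bins
  ))
  total <- sum(counts)
  out <- tibble(
    class = paste0(edges[-(n_bins + 1)], "-", edges[-1]),
    count = counts,
    per_mm2 = counts / result$inspected_area_mm2,
    cumulative_pct = if (total > 0) 100 * cumsum(counts) / total else
      rep(NA_real_, n_bins)
  )
  class(out) <- c("class_histogram", class(out))
  attr(out, "imaged_area_mm2") <- result$inspected_area_mm2
  out
}
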