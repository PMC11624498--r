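#' Skeletonize a vessel mask into a branch/junction graph
#'
#' Thins the binary vessel mask to a 26-connected curve skeleton (sequential
#' removal of topology-preserving simple points, ordered by distance to the
#' mask boundary so the skeleton stays centred), classifies skeleton voxels
#' by their number of skeleton neighbours (1 = endpoint, 2 = slab,
#' >= 3 = junction), clusters adjacent junction voxels into single nodes,
#' traces slab chains between nodes into branches, and attaches a per-point
#' radius from the Euclidean distance transform of the mask. Spur branches
#' shorter than `prune_um` are removed and the graph re-derived (degree-2
#' nodes dissolved) until stable; junction nodes connected by branches
#' shorter than `merge_um` are merged.
#'
#' @param vessel_mask logical 3D array (z, y, x).
#' @param spacing voxel spacing `(dz, dy, dx)` in um (scalar = isotropic).
#' @param prune_um spur-pruning length threshold, um.
#' @param merge_um junction-merge distance, um (default two voxels).
#' @return An object of class `vessel_graph`: list with `nodes` (data frame
#'   `id, z, y, x, kind, degree`), `branches` (list of `points` n x 3 um
#'   matrix, `radius` per point, `from`, `to`, `type` in J2J/J2E/E2E) and
#'   `spacing`. An empty mask yields an empty graph.
#' @export
skeletonize_graph <- function(vessel_mask, spacing = 10, prune_um = 50,
                              merge_um = NULL) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  merge_um <- merge_um %||% (2 * max(spacing))
  dims <- dim(vessel_mask)
  if (!any(vessel_mask))
    return(empty_graph(spacing))
  skel <- cpp_thin3d(as.logical(vessel_mask), as.integer(dims), spacing)
  dim(skel) <- dims
  rmap <- sqrt(cpp_edt3d(as.logical(vessel_mask), as.integer(dims), spacing))
  dim(rmap) <- dims
  g <- graph_from_skeleton(skel, rmap, spacing)
  g <- prune_graph(g, prune_um, merge_um)
  g
}

empty_graph <- function(spacing) {
  structure(list(nodes = data.frame(id = integer(), z = double(),
                                    y = double(), x = double(),
                                    kind = character(), degree = integer()),
                 branches = list(), spacing = spacing),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  tt <- table(factor(vapply(x$branches, `[[`, "", "type"),
                     levels = c("J2J", "J2E", "E2E")))
  cat(sprintf("<vessel_graph> %d branches (J2J %d, J2E %d, E2E %d), %d junctions, %d endpoints\n",
              length(x$branches), tt["J2J"], tt["J2E"], tt["E2E"],
              sum(x$nodes$kind == "junction"),
              sum(x$nodes$kind == "endpoint")))
  invisible(x)
}

# build the raw graph from a thinned skeleton; voxel centres at
# (i - 0.5) * spacing
graph_from_skeleton <- function(skel, rmap, spacing) {
  dims <- dim(skel)
  lin <- which(skel)                       # linear indices, sorted
  if (length(lin) == 0L) return(empty_graph(spacing))
  cnt <- cpp_neighbour_count(skel, as.integer(dims))
  dim(cnt) <- dims
  nvox <- length(lin)
  coord <- arrayInd(lin, dims)             # (z, y, x) 1-based

  # adjacency among skeleton voxels via linear-index matching
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  adj <- vector("list", nvox)
  for (k in seq_len(nrow(offs))) {
    nb <- coord + matrix(offs[k, ], nvox, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nl <- rep(NA_integer_, nvox)
    nl[ok] <- (nb[ok, 3] - 1L) * dims[1] * dims[2] +
      (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
    m <- match(nl, lin)
    hit <- which(!is.na(m))
    for (i in hit) adj[[i]] <- c(adj[[i]], m[i])
  }

  vcnt <- cnt[lin]
  is_nodevox <- vcnt != 2L                 # endpoints, isolated, junctions
  # cluster adjacent junction voxels (>=3 neighbours) into one node each
  jvox <- array(FALSE, dims)
  jvox[lin[vcnt >= 3L]] <- TRUE
  jlab_full <- cpp_label3d(jvox, as.integer(dims))
  jlab <- jlab_full[lin]                   # 0 for non-junction voxels

  node_of <- integer(nvox)                 # node id per voxel (0 = slab)
  nodes <- list()
  for (cl in seq_len(max(jlab, 0L))) {
    members <- which(jlab == cl)
    id <- length(nodes) + 1L
    node_of[members] <- id
    cm <- colMeans(coord[members, , drop = FALSE])
    nodes[[id]] <- list(z = (cm[1] - 0.5) * spacing[1],
                        y = (cm[2] - 0.5) * spacing[2],
                        x = (cm[3] - 0.5) * spacing[3],
                        radius = max(rmap[lin[members]]))
  }
  for (i in which(vcnt <= 1L)) {           # endpoint / isolated voxels
    id <- length(nodes) + 1L
    node_of[i] <- id
    nodes[[id]] <- list(z = (coord[i, 1] - 0.5) * spacing[1],
                        y = (coord[i, 2] - 0.5) * spacing[2],
                        x = (coord[i, 3] - 0.5) * spacing[3],
                        radius = rmap[lin[i]])
  }
  n_nodes <- length(nodes)
  node_xyz <- if (n_nodes)
    t(vapply(nodes, function(n) c(n$z, n$y, n$x), double(3))) else
    matrix(0, 0, 3)

  vox_um <- cbind((coord[, 1] - 0.5) * spacing[1],
                  (coord[, 2] - 0.5) * spacing[2],
                  (coord[, 3] - 0.5) * spacing[3])
  vox_r <- rmap[lin]

  branches <- list()
  visited <- logical(nvox)                 # slab voxels consumed by a trace
  seen_pair <- character(0)                # dedupe direct node-node contacts

  add_branch <- function(from, to, chain) {
    pts <- rbind(node_xyz[from, ],
                 if (length(chain)) vox_um[chain, , drop = FALSE],
                 node_xyz[to, ])
    rr <- c(nodes[[from]]$radius,
            if (length(chain)) vox_r[chain], nodes[[to]]$radius)
    branches[[length(branches) + 1L]] <<-
      list(points = unname(pts), radius = unname(rr), from = from, to = to)
  }

  for (v in order(lin)) {
    if (node_of[v] == 0L) next
    for (u in adj[[v]]) {
      if (node_of[u] == node_of[v] && node_of[u] != 0L) next
      if (node_of[u] != 0L) {              # direct node-node adjacency
        key <- paste(sort(c(lin[v], lin[u])), collapse = "-")
        if (key %in% seen_pair) next
        seen_pair <- c(seen_pair, key)
        add_branch(node_of[v], node_of[u], integer(0))
      } else if (!visited[u]) {            # start of a slab chain
        chain <- integer(0)
        prev <- v
        cur <- u
        repeat {
          visited[cur] <- TRUE
          chain <- c(chain, cur)
          nxt <- setdiff(adj[[cur]], prev)
          # prefer slab continuation; a slab voxel has exactly two skeleton
          # neighbours, but one of them may sit inside a junction cluster
          if (length(nxt) == 0L) {         # dead end without node voxel
            id <- length(nodes) + 1L
            nodes[[id]] <- list(z = vox_um[cur, 1], y = vox_um[cur, 2],
                                x = vox_um[cur, 3], radius = vox_r[cur])
            node_xyz <- rbind(node_xyz, vox_um[cur, ])
            node_of[cur] <- id
            chain <- chain[-length(chain)]
            add_branch(node_of[v], id, chain)
            break
          }
          nxt <- nxt[1L]
          if (node_of[nxt] != 0L) {
            add_branch(node_of[v], node_of[nxt], chain)
            break
          }
          prev <- cur
          cur <- nxt
        }
      }
    }
  }

  # pure cycles: unvisited slab voxels form closed loops; break each at its
  # lexicographically smallest voxel, which becomes a node with from == to
  for (v in order(lin)) {
    if (node_of[v] != 0L || visited[v]) next
    id <- length(nodes) + 1L
    nodes[[id]] <- list(z = vox_um[v, 1], y = vox_um[v, 2],
                        x = vox_um[v, 3], radius = vox_r[v])
    node_xyz <- rbind(node_xyz, vox_um[v, ])
    node_of[v] <- id
    chain <- integer(0)
    prev <- v
    cur <- adj[[v]][1L]
    while (node_of[cur] == 0L) {
      visited[cur] <- TRUE
      chain <- c(chain, cur)
      nxt <- setdiff(adj[[cur]], prev)
      if (length(nxt) == 0L) break
      prev <- cur
      cur <- nxt[1L]
    }
    add_branch(id, id, chain)
  }

  finalize_graph(nodes, branches, spacing)
}

# assemble node table, degrees, kinds and branch types
finalize_graph <- function(nodes, branches, spacing) {
  n <- length(nodes)
  deg <- integer(n)
  for (b in branches) {
    deg[b$from] <- deg[b$from] + 1L
    deg[b$to] <- deg[b$to] + 1L
  }
  kind <- ifelse(deg >= 3L, "junction", "endpoint")
  nd <- data.frame(id = seq_len(n),
                   z = vapply(nodes, `[[`, 0, "z"),
                   y = vapply(nodes, `[[`, 0, "y"),
                   x = vapply(nodes, `[[`, 0, "x"),
                   kind = kind, degree = deg)
  branches <- lapply(branches, function(b) {
    ends <- sort(kind[c(b$from, b$to)])
    b$type <- if (identical(ends, c("junction", "junction"))) "J2J"
              else if (identical(ends, c("endpoint", "junction"))) "J2E"
              else "E2E"
    b
  })
  keep <- deg > 0L
  g <- structure(list(nodes = nd[keep, , drop = FALSE], branches = branches,
                      spacing = spacing, .radius = vapply(nodes, `[[`, 0,
                                                          "radius")),
                 class = "vessel_graph")
  g
}

branch_length <- function(b) {
  if (nrow(b$points) < 2L) return(0)
  sum(sqrt(rowSums(diff(b$points)^2)))
}

# spur removal + degree-2 dissolution + short-junction merge, iterated
prune_graph <- function(g, prune_um, merge_um) {
  repeat {
    n <- max(c(0L, vapply(g$branches, function(b) max(b$from, b$to), 0L)))
    deg <- integer(n)
    for (b in g$branches) {
      deg[b$from] <- deg[b$from] + 1L
      deg[b$to] <- deg[b$to] + 1L
    }
    lens <- vapply(g$branches, branch_length, 0)
    is_spur <- vapply(seq_along(g$branches), function(i) {
      b <- g$branches[[i]]
      if (b$from == b$to) return(FALSE)
      ends1 <- deg[b$from] == 1L
      ends2 <- deg[b$to] == 1L
      lens[i] < prune_um && (ends1 || ends2)
    }, logical(1))
    if (!any(is_spur)) break
    g$branches <- g$branches[!is_spur]
    g <- dissolve_degree2(g)
  }
  g <- merge_close_junctions(g, merge_um)
  g <- dissolve_degree2(g)
  rebuild_nodes(g)
}

dissolve_degree2 <- function(g) {
  repeat {
    n <- max(c(0L, vapply(g$branches, function(b) max(b$from, b$to), 0L)))
    if (n == 0L) break
    inc <- vector("list", n)
    for (i in seq_along(g$branches)) {
      b <- g$branches[[i]]
      inc[[b$from]] <- c(inc[[b$from]], i)
      inc[[b$to]] <- c(inc[[b$to]], i)
    }
    deg <- lengths(inc)
    cand <- which(deg == 2L & vapply(inc, function(x)
      length(unique(x)) == 2L, logical(1)))
    if (length(cand) == 0L) break
    v <- cand[1L]
    i1 <- inc[[v]][1L]; i2 <- inc[[v]][2L]
    b1 <- g$branches[[i1]]; b2 <- g$branches[[i2]]
    # orient b1 to end at v, b2 to start at v
    if (b1$to != v) {
      b1$points <- b1$points[nrow(b1$points):1, , drop = FALSE]
      b1$radius <- rev(b1$radius)
      tmp <- b1$from; b1$from <- b1$to; b1$to <- tmp
    }
    if (b2$from != v) {
      b2$points <- b2$points[nrow(b2$points):1, , drop = FALSE]
      b2$radius <- rev(b2$radius)
      tmp <- b2$from; b2$from <- b2$to; b2$to <- tmp
    }
    merged <- list(points = rbind(b1$points,
                                  b2$points[-1, , drop = FALSE]),
                   radius = c(b1$radius, b2$radius[-1]),
                   from = b1$from, to = b2$to)
    g$branches[[i1]] <- merged
    g$branches[[i2]] <- NULL
  }
  g
}

merge_close_junctions <- function(g, merge_um) {
  repeat {
    n <- max(c(0L, vapply(g$branches, function(b) max(b$from, b$to), 0L)))
    if (n == 0L) break
    deg <- integer(n)
    for (b in g$branches) {
      deg[b$from] <- deg[b$from] + 1L
      deg[b$to] <- deg[b$to] + 1L
    }
    hit <- 0L
    for (i in seq_along(g$branches)) {
      b <- g$branches[[i]]
      if (b$from != b$to && deg[b$from] >= 3L && deg[b$to] >= 3L &&
          branch_length(b) < merge_um) { hit <- i; break }
    }
    if (hit == 0L) break
    b <- g$branches[[hit]]
    keep <- min(b$from, b$to); drop <- max(b$from, b$to)
    g$branches[[hit]] <- NULL
    g$branches <- lapply(g$branches, function(bb) {
      if (bb$from == drop) bb$from <- keep
      if (bb$to == drop) bb$to <- keep
      bb
    })
  }
  g
}

# rebuild the node table from whatever node ids the branches still
# reference, preserving coordinates where known (branch end points)
rebuild_nodes <- function(g) {
  ids <- sort(unique(unlist(lapply(g$branches, function(b) c(b$from, b$to)))))
  if (length(ids) == 0L) return(empty_graph(g$spacing))
  remap <- stats::setNames(seq_along(ids), ids)
  nodes <- vector("list", length(ids))
  deg <- integer(length(ids))
  for (b in g$branches) {
    f <- remap[[as.character(b$from)]]
    t <- remap[[as.character(b$to)]]
    nodes[[f]] <- list(z = b$points[1, 1], y = b$points[1, 2],
                       x = b$points[1, 3], radius = b$radius[1])
    nodes[[t]] <- list(z = b$points[nrow(b$points), 1],
                       y = b$points[nrow(b$points), 2],
                       x = b$points[nrow(b$points), 3],
                       radius = b$radius[length(b$radius)])
    deg[f] <- deg[f] + 1L
    deg[t] <- deg[t] + 1L
  }
  branches <- lapply(g$branches, function(b) {
    b$from <- remap[[as.character(b$from)]]
    b$to <- remap[[as.character(b$to)]]
    b
  })
  finalize_graph(nodes, branches, g$spacing)
}
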