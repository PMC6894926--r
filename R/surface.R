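#' Toy cortical surface meshes
#'
#' The pipeline's surface machinery (searchlights, cluster inference) needs a
#' closed triangulated mesh with an edge-adjacency graph. `make_toy_surface()`
#' builds an icosphere — an icosahedron subdivided `subdivisions` times with
#' vertices projected back onto the unit sphere — and optionally paints
#' edge-connected "regions" onto it by breadth-first growth from random seed
#' vertices. An icosphere with `s` subdivisions has `10 * 4^s + 2` vertices
#' and `20 * 4^s` faces.
#'
#' @param subdivisions number of 4-to-1 triangle subdivisions (>= 0; the
#'   meshes used in practice have >= 2)
#' @param n_regions number of labelled regions to paint (0 = none)
#' @param region_size vertices per region
#' @param seed RNG seed for region placement
#' @return a `toy_surface`: list with `vertices` (m x 3), `faces` (t x 3
#'   integer), `region_map` (length-m integer, 0 = background) and `adjacency`
#'   (list of integer neighbor vectors)
#' @export
make_toy_surface <- function(subdivisions = 2, n_regions = 0,
                             region_size = 30, seed = 1) {
  stop_if(subdivisions < 0, "subdivisions must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(6, 5, 10), c(12, 3, 5), c(11, 7, 3), c(8, 9, 7), c(2, 10, 9)
  )
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      p <- (v[a, ] + v[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      idx <- nrow(v)
      mid_cache[[key]] <- idx
      idx
    }
    newf <- matrix(0L, nrow(f) * 4, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[(i - 1) * 4 + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    f <- newf
  }
  m <- nrow(v)
  adj <- mesh_adjacency(f, m)
  region_map <- integer(m)
  if (n_regions > 0) {
    stop_if(n_regions * region_size > m,
            "cannot place %d regions of %d vertices on a %d-vertex mesh",
            n_regions, region_size, m)
    region_map <- with_seed(seed, grow_regions(adj, v, n_regions, region_size))
  }
  structure(
    list(vertices = v, faces = f, region_map = region_map, adjacency = adj),
    class = "toy_surface"
  )
}

# Edge-adjacency list from a face matrix.
mesh_adjacency <- function(faces, n_vertices) {
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  adj <- split(e[, 2], factor(e[, 1], levels = seq_len(n_vertices)))
  lapply(adj, function(x) sort(unique(as.integer(x))))
}

# Grow n compact edge-connected regions of fixed size: random seed vertex,
# then repeatedly annex the unassigned neighbor closest (Euclidean) to the
# seed, giving near-circular patches with minimal boundary. Deterministic
# under the caller's RNG state.
grow_regions <- function(adj, vertices, n_regions, region_size) {
  m <- length(adj)
  region_map <- integer(m)
  order_all <- sample.int(m)
  seeds <- integer(0)
  for (cand in order_all) {
    if (length(seeds) == n_regions) break
    if (region_map[cand] != 0) next
    # keep seeds well apart: skip candidates adjacent to an existing region
    if (any(region_map[adj[[cand]]] != 0)) next
    rid <- length(seeds) + 1L
    members <- cand
    region_map[cand] <- rid
    while (length(members) < region_size) {
      nb <- setdiff(unique(unlist(adj[members])), members)
      nb <- nb[region_map[nb] == 0]
      if (length(nb) == 0) break
      d <- colSums((t(vertices[nb, , drop = FALSE]) - vertices[cand, ])^2)
      take <- nb[order(d, nb)][1]
      members <- c(members, take)
      region_map[take] <- rid
    }
    if (length(members) < region_size) {
      # dead-ended against another region; undo and try a different seed
      region_map[region_map == rid] <- 0L
      next
    }
    seeds <- c(seeds, cand)
  }
  stop_if(length(seeds) < n_regions,
          "could not place %d regions of %d vertices", n_regions, region_size)
  region_map
}

#' @export
print.toy_surface <- function(x, ...) {
  cat(sprintf("<toy_surface> %d vertices, %d faces, %d region(s)\n",
              nrow(x$vertices), nrow(x$faces), max(x$region_map)))
  invisible(x)
}

#' Euler characteristic of a mesh (V - E + F); 2 for a closed sphere
#' @param surface a `toy_surface`
#' @export
euler_characteristic <- function(surface) {
  ne <- sum(lengths(surface$adjacency)) / 2
  nrow(surface$vertices) - ne + nrow(surface$faces)
}

#' Write a toy surface as Wavefront OBJ
#' @param surface a `toy_surface`
#' @param path output file
#' @export
write_surface_obj <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.8f %.8f %.8f", surface$vertices[, 1],
                     surface$vertices[, 2], surface$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", surface$faces[, 1], surface$faces[, 2],
                     surface$faces[, 3]), con)
  invisible(path)
}

#' Build one searchlight per vertex
#'
#' A searchlight is the set of `n_features` vertices nearest to a center
#' vertex by breadth-first edge-hop distance, mirroring a surface-based
#' geodesic neighborhood. Within the last partially-used hop ring, ties are
#' broken by Euclidean distance to the center and then by vertex index, so
#' the construction is deterministic. Centers on components smaller than
#' `n_features` get all reachable vertices and are flagged.
#'
#' @param surface a `toy_surface`
#' @param n_features number of vertices per searchlight (center + neighbors)
#' @return tibble with columns `center` (int), `members` (list of int),
#'   `n_members`, `complete` (logical)
#' @export
build_searchlights <- function(surface, n_features = 100) {
  m <- nrow(surface$vertices)
  stop_if(n_features < 1 || n_features > m,
          "n_features must be in [1, %d]", m)
  adj <- surface$adjacency
  vx <- surface$vertices
  members <- vector("list", m)
  for (center in seq_len(m)) {
    sel <- searchlight_members(adj, vx, center, n_features)
    members[[center]] <- sel
  }
  n_mem <- lengths(members)
  tibble(center = seq_len(m), members = members, n_members = n_mem,
         complete = n_mem == n_features)
}

# BFS ring expansion with within-ring Euclidean tie-break.
searchlight_members <- function(adj, vertices, center, n_features) {
  visited <- center
  ring <- center
  while (length(visited) < n_features) {
    nxt <- setdiff(unique(unlist(adj[ring])), visited)
    if (length(nxt) == 0) break
    if (length(visited) + length(nxt) > n_features) {
      d <- sqrt(colSums((t(vertices[nxt, , drop = FALSE]) -
                           vertices[center, ])^2))
      nxt <- nxt[order(d, nxt)][seq_len(n_features - length(visited))]
    }
    visited <- c(visited, sort(nxt))
    ring <- nxt
  }
  as.integer(visited)
}
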