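## Deterministic icosphere meshes and a synthetic 8-network atlas, standing
## in for an MRI-derived cortical surface at test scale.

#' Icosphere triangulation
#'
#' Subdivides a regular icosahedron `subdiv` times, projecting onto the unit
#' sphere, giving `10 * 4^subdiv + 2` quasi-uniform vertices.
#'
#' @param subdiv Number of subdivision rounds (0 = icosahedron).
#' @return List with `vertices` (V x 3, unit norm) and `faces` (F x 3 indices).
#' @export
icosphere <- function(subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- lapply(seq_len(nv), function(i) v[i, ])
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- vlist[[i]] + vlist[[j]]
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1]] <<- m
      idx <- length(vlist)
      mid_cache[[key]] <- idx
      idx
    }
    newf <- matrix(0L, nrow(f) * 4, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[(t - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- newf
  }
  list(vertices = v, faces = f)
}

#' Spherical cortical source mesh
#'
#' An icosphere scaled to `radius` (inside the innermost head-model shell),
#' with outward radial dipole normals and the triangulation's vertex
#' adjacency matrix.
#'
#' @param subdiv Icosphere subdivision level (see [icosphere()]).
#' @param radius Mesh radius (default 0.8, inside the default brain shell).
#' @return Object of class `cortical_mesh`: `vertices` (V x 3), `normals`
#'   (V x 3 unit), `adjacency` (V x V sparse symmetric 0/1), `faces`.
#' @export
cortical_mesh <- function(subdiv = 3, radius = 0.8) {
  ico <- icosphere(subdiv)
  V <- nrow(ico$vertices)
  e <- rbind(ico$faces[, 1:2], ico$faces[, 2:3], ico$faces[, c(3, 1)])
  adj <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                              x = 1, dims = c(V, V), use.last.ij = TRUE)
  adj <- methods::as(adj, "CsparseMatrix")
  adj@x[] <- 1
  structure(list(vertices = ico$vertices * radius, normals = ico$vertices,
                 adjacency = adj, faces = ico$faces),
            class = "cortical_mesh")
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat(sprintf("<cortical_mesh> %d vertices, %d faces, radius %.3g\n",
              nrow(x$vertices), nrow(x$faces), sqrt(sum(x$vertices[1, ]^2))))
  invisible(x)
}

#' Synthetic large-scale-network atlas
#'
#' Partitions mesh vertices into eight contiguous patches by
#' nearest-seed-direction assignment. Seed directions are placed at
#' anatomically inspired locations on the sphere (visual occipital,
#' somatomotor at the vertex, dorsal attention parietal, ventral attention
#' right temporal, limbic orbitofrontal-inferior, frontoparietal left
#' lateral, default medial prefrontal, deep at the inferior cap far from
#' the electrodes, mimicking the poor visibility of deep structures). The
#' geometry is synthetic and carries no anatomical claim beyond that
#' orientation.
#'
#' @param mesh A [cortical_mesh()].
#' @param n_networks Number of patches (default and maximum 8).
#' @param seed Unused (partition is deterministic); kept for call
#'   compatibility.
#' @return Object of class `network_atlas`: integer `labels` per vertex and
#'   `names`.
#' @export
synthetic_atlas <- function(mesh, n_networks = 8, seed = 1L) {
  V <- nrow(mesh$vertices)
  stop_if(n_networks < 1 || n_networks > 8, "n_networks must be in 1..8")
  ## +y nasion, +x right ear, +z vertex
  dirs <- rbind(
    visual = c(0, -1, -0.1),
    somatomotor = c(0, 0.1, 1),
    `dorsal attention` = c(0, -0.65, 0.75),
    `ventral attention` = c(0.95, 0.25, 0.1),
    limbic = c(0, 0.85, -0.5),
    frontoparietal = c(-0.95, 0.25, 0.1),
    default = c(0, 0.9, 0.45),
    deep = c(0, 0.15, -1))[seq_len(n_networks), , drop = FALSE]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  S <- (mesh$vertices / sqrt(rowSums(mesh$vertices^2))) %*% t(dirs)
  labels <- max.col(S, ties.method = "first")
  stop_if(length(unique(labels)) != n_networks,
          "empty network in atlas partition")
  structure(list(labels = labels, names = rownames(dirs)),
            class = "network_atlas")
}

#' @export
print.network_atlas <- function(x, ...) {
  cat("<network_atlas>", length(x$labels), "vertices in",
      length(x$names), "networks\n")
  print(table(factor(x$labels, labels = x$names)))
  invisible(x)
}
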