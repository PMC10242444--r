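# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All generators route their randomness through this.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    stop(sprintf("'%s' must be a single finite number >= %s", name, min),
         call. = FALSE)
  }
  invisible(x)
}

stopifnot_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a fraction in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

# Draw from a scalar or a length-2 range (uniform). Used for parameter
# fields that accept either a fixed value or a range.
draw_range <- function(x, n = 1L) {
  if (length(x) == 1L) rep(x, n) else runif(n, min(x), max(x))
}

# 8-connected components of a sparse pixel set, restricted so that two
# pixels connect only when they carry the same group id (here: nucleus
# label). `idx` are linear indices into an ny x nx matrix. Returns an
# integer component id per pixel (1..K, in no particular order).
# EBImage::bwlabel is 4-connected, hence this union-find on the sparse set.
label_components_8 <- function(idx, group, ny, nx) {
  k <- length(idx)
  if (k == 0L) return(integer(0))
  ord <- order(idx)
  idx <- idx[ord]
  group <- group[ord]
  pos <- integer(ny * nx)  # sparse lookup: linear index -> rank in idx
  pos[idx] <- seq_len(k)
  y <- ((idx - 1L) %% ny) + 1L
  x <- ((idx - 1L) %/% ny) + 1L

  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  offs <- cbind(dy = c(-1L, -1L, -1L, 0L), dx = c(-1L, 0L, 1L, -1L))
  for (o in seq_len(nrow(offs))) {
    yn <- y + offs[o, 1L]
    xn <- x + offs[o, 2L]
    ok <- yn >= 1L & yn <= ny & xn >= 1L & xn <= nx
    if (!any(ok)) next
    nb <- (xn[ok] - 1L) * ny + yn[ok]
    j <- pos[nb]
    i <- which(ok)[j > 0L]
    j <- j[j > 0L]
    same <- group[i] == group[j]
    i <- i[same]; j <- j[same]
    for (e in seq_along(i)) {
      ri <- find(i[e]); rj <- find(j[e])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  comp <- match(roots, unique(roots))
  comp[order(ord)] <- comp
  comp
}

# Maximum-intensity projection over the z dimension of an ny x nx x nz array.
max_project <- function(a) {
  stopifnot(length(dim(a)) == 3L)
  out <- a[, , 1L]
  nz <- dim(a)[3L]
  if (nz > 1L) for (z in 2L:nz) out <- pmax(out, a[, , z])
  out
}

write_records <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_records <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
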