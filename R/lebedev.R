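## Lebedev angular grids, loaded from plain-text tables shipped with the
## package.  Weights are normalized to sum to one; multiplying by
## 4*pi*r^2 gives surface-element areas on a sphere of radius r.

.lebedev_cache <- new.env(parent = emptyenv())

#' Supported Lebedev grid sizes
#'
#' @return integer vector of available points-per-sphere counts.
#' @export
lebedev_orders <- function() {
  files <- list.files(system.file("extdata", "lebedev", package = "hipres"),
                      pattern = "^ld[0-9]+\\.txt$")
  sort(as.integer(sub("^ld0*([0-9]+)\\.txt$", "\\1", files)))
}

#' Load a Lebedev angular grid
#'
#' @param n number of grid points (one of [lebedev_orders()]).
#' @return list with `points` (n x 3 unit vectors) and `weights`
#'   (length n, summing to 1).
#' @export
lebedev_grid <- function(n) {
  key <- as.character(n)
  if (!is.null(.lebedev_cache[[key]])) return(.lebedev_cache[[key]])
  path <- system.file("extdata", "lebedev", sprintf("ld%04d.txt", n), package = "hipres")
  if (!nzchar(path) || !file.exists(path))
    stop("unsupported Lebedev grid size ", n, "; available: ",
         paste(lebedev_orders(), collapse = ", "))
  tab <- utils::read.table(path, comment.char = "#")
  g <- list(points = as.matrix(tab[, 1:3]), weights = tab[, 4])
  dimnames(g$points) <- NULL
  .lebedev_cache[[key]] <- g
  g
}
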