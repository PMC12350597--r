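## 2D cubical homology of binary rasters.
##
## b0 counts foreground connected components under the foreground adjacency;
## b1 counts holes, i.e. background components (under the background
## adjacency) that contain no border pixel. The two phases use dual
## adjacencies (8/4 by default) so that component and hole counts are
## consistent; no padding ring is added.

checkBinary <- function(img) {
  if (!is.matrix(img)) stop("binary image must be a matrix")
  if (nrow(img) < 1 || ncol(img) < 1) stop("binary image must be non-empty")
  if (is.logical(img)) return(img)
  v <- unique(as.vector(img))
  if (!all(v %in% c(0, 1))) stop("binary image must be two-valued (logical or 0/1)")
  img == 1
}

#' Betti numbers of a 2D binary image
#'
#' Computes the pair (b0, b1) of a binary raster: b0 is the number of
#' connected foreground components, b1 the number of holes (background
#' components, under the dual adjacency, that do not reach the image
#' border). \code{floodFillBetti} is an independent pure-R implementation
#' (breadth-first queue fill) of the same contract, kept for cross-checking;
#' \code{eulerCharacteristic} computes the Euler characteristic
#' chi = b0 - b1 locally from 2x2 bit-quad counts (Gray's method).
#'
#' @param img logical (or strict 0/1) matrix; \code{TRUE} = foreground.
#' @param conn a \linkS4class{ConnectivityRule}.
#' @return \code{bettiNumbers}, \code{floodFillBetti}: named integer vector
#'   \code{c(b0 = , b1 = )}. \code{eulerCharacteristic}: integer.
#' @examples
#' ring <- matrix(TRUE, 5, 5); ring[2:4, 2:4] <- FALSE; ring[3, 3] <- FALSE
#' ring[2:4, 2:4][c(1, 3, 7, 9)] <- TRUE  # keep it an annulus
#' ann <- matrix(FALSE, 5, 5); ann[2:4, 2:4] <- TRUE; ann[3, 3] <- FALSE
#' bettiNumbers(ann)                      # one component, one hole
#' eulerCharacteristic(ann)               # 0
#' @export
bettiNumbers <- function(img, conn = connectivityRule()) {
  img <- checkBinary(img)
  b <- .cppBetti(img, conn@foreground == 8L, conn@background == 8L)
  c(b0 = b[1], b1 = b[2])
}

#' @rdname bettiNumbers
#' @export
floodFillBetti <- function(img, conn = connectivityRule()) {
  img <- checkBinary(img)
  nr <- nrow(img); nc <- ncol(img)

  neighbours <- function(i, eight) {
    r <- ((i - 1L) %% nr) + 1L
    cc <- ((i - 1L) %/% nr) + 1L
    if (eight) {
      dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
      dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
    } else {
      dr <- c(-1L, 1L, 0L, 0L)
      dc <- c(0L, 0L, -1L, 1L)
    }
    rr <- r + dr; cn <- cc + dc
    ok <- rr >= 1L & rr <= nr & cn >= 1L & cn <= nc
    (cn[ok] - 1L) * nr + rr[ok]
  }

  countFill <- function(phase, eight, excludeBorder) {
    todo <- which(as.vector(img) == phase)
    seen <- rep(FALSE, nr * nc)
    count <- 0L
    for (start in todo) {
      if (seen[start]) next
      queue <- start
      seen[start] <- TRUE
      touches <- FALSE
      while (length(queue)) {
        i <- queue[[1L]]
        queue <- queue[-1L]
        r <- ((i - 1L) %% nr) + 1L
        cc <- ((i - 1L) %/% nr) + 1L
        if (r == 1L || r == nr || cc == 1L || cc == nc) touches <- TRUE
        nb <- neighbours(i, eight)
        nb <- nb[img[nb] == phase & !seen[nb]]
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
      if (!excludeBorder || !touches) count <- count + 1L
    }
    count
  }

  c(b0 = countFill(TRUE, conn@foreground == 8L, FALSE),
    b1 = countFill(FALSE, conn@background == 8L, TRUE))
}

#' @rdname bettiNumbers
#' @export
eulerCharacteristic <- function(img, conn = connectivityRule()) {
  img <- checkBinary(img)
  .cppEuler(img, conn@foreground == 8L)
}
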