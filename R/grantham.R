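## The standard Grantham (1974) amino-acid substitution distance matrix,
## embedded as its published upper triangle. Distances combine composition,
## polarity and molecular volume differences on a 0-215 scale (mean 100
## over all residue pairs); the largest published distance is Cys-Trp = 215.
GRANTHAM_ORDER <- c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
                    "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W")

GRANTHAM_UPPER <- list(
  S = c(110, 145, 74, 58, 99, 124, 56, 142, 155, 144, 112, 89, 68, 46,
        121, 65, 80, 135, 177),
  R = c(102, 103, 71, 112, 96, 125, 97, 97, 77, 180, 29, 43, 86, 26, 96,
        54, 91, 101),
  L = c(98, 92, 96, 32, 138, 5, 22, 36, 198, 99, 113, 153, 107, 172, 138,
        15, 61),
  P = c(38, 27, 68, 42, 95, 114, 110, 169, 77, 76, 91, 103, 108, 93, 87,
        147),
  T = c(58, 69, 59, 89, 103, 92, 149, 47, 42, 65, 78, 85, 65, 81, 128),
  A = c(64, 60, 94, 113, 112, 195, 86, 91, 111, 106, 126, 107, 84, 148),
  V = c(109, 29, 50, 55, 192, 84, 96, 133, 97, 152, 121, 21, 88),
  G = c(135, 153, 147, 159, 98, 87, 80, 127, 94, 98, 127, 184),
  I = c(21, 33, 198, 94, 109, 149, 102, 168, 134, 10, 61),
  F = c(22, 205, 100, 116, 158, 102, 177, 140, 28, 40),
  Y = c(194, 83, 99, 143, 85, 160, 122, 36, 37),
  C = c(174, 154, 139, 202, 154, 170, 196, 215),
  H = c(24, 68, 32, 81, 40, 87, 115),
  Q = c(46, 53, 61, 29, 101, 130),
  N = c(94, 23, 42, 142, 174),
  K = c(101, 56, 95, 110),
  D = c(45, 160, 181),
  E = c(126, 152),
  M = c(67))

#' The embedded Grantham distance matrix
#'
#' @return the symmetric 20x20 integer matrix of Grantham (1974) amino-acid
#'   substitution distances, rows/columns named by one-letter residue codes.
#' @export
grantham_matrix <- function() {
  n <- length(GRANTHAM_ORDER)
  m <- matrix(0L, n, n, dimnames = list(GRANTHAM_ORDER, GRANTHAM_ORDER))
  for (i in seq_len(n - 1)) {
    vals <- GRANTHAM_UPPER[[GRANTHAM_ORDER[i]]]
    for (off in seq_along(vals)) {
      j <- i + off
      m[i, j] <- m[j, i] <- as.integer(vals[off])
    }
  }
  m
}

GRANTHAM_CATEGORIES <- c("conservative", "moderately_conservative",
                         "moderately_radical", "radical")

#' Grantham substitution distance and category
#'
#' Physicochemical dissimilarity of an amino-acid substitution from the
#' embedded standard matrix, binned into the four conventional categories:
#' distances up to the first boundary are conservative, then moderately
#' conservative, moderately radical, and radical at or above the last
#' boundary (defaults 0-50 / 51-100 / 101-150 / >= 151).
#'
#' @param aa_from,aa_to one-letter codes of the 20 standard residues
#'   (vectorized; pairs are matched elementwise).
#' @param bins three strictly increasing category boundaries.
#' @return data.frame with integer `distance` and factor `category`.
#' @export
grantham <- function(aa_from, aa_to, bins = c(50, 100, 150)) {
  aa_from <- toupper(as.character(aa_from))
  aa_to <- toupper(as.character(aa_to))
  if (length(aa_from) != length(aa_to)) {
    stop("aa_from and aa_to must have the same length", call. = FALSE)
  }
  bad <- !aa_from %in% GRANTHAM_ORDER | !aa_to %in% GRANTHAM_ORDER
  if (any(bad)) {
    stop("non-standard residue code(s): ",
         paste(unique(c(aa_from[bad], aa_to[bad])), collapse = ", "),
         call. = FALSE)
  }
  m <- grantham_matrix()
  d <- m[cbind(aa_from, aa_to)]
  category <- cut(d, breaks = c(-Inf, bins, Inf),
                  labels = GRANTHAM_CATEGORIES, right = TRUE)
  data.frame(distance = as.integer(d), category = category)
}
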