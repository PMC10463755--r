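#' Parse a SMILES string into an atom/bond table
#'
#' Wraps ChemmineR/OpenBabel: the SMILES is converted to an SDF with
#' generated 2D depiction coordinates, from which element symbols,
#' coordinates and a bond list (with orders) are extracted. Implicit
#' hydrogen counts are derived from standard valences minus the summed
#' bond orders, which is adequate for the neutral, drug-like molecules the
#' package targets.
#'
#' @param smiles A single SMILES string.
#' @return List with `atoms` (data.frame: `element`, `x`, `y`, `n_h`,
#'   `degree`) and `bonds` (data.frame: `a1`, `a2`, `order`); atom indices
#'   are 1-based in SMILES order.
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) stop_featurize("cannot parse SMILES '", smiles, "'"))
  mol <- sdf[[1L]]
  ab <- ChemmineR::atomblock(mol)
  elements <- sub("_.*$", "", rownames(ab))
  n <- nrow(ab)
  bb <- ChemmineR::bondblock(mol)
  if (NROW(bb) == 0L || NCOL(bb) < 3L) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  } else {
    bonds <- data.frame(a1 = as.integer(bb[, 1L]), a2 = as.integer(bb[, 2L]),
                        order = as.integer(bb[, 3L]))
  }
  valence_sum <- numeric(n)
  degree <- integer(n)
  if (nrow(bonds) > 0L) {
    for (i in seq_len(nrow(bonds))) {
      o <- bonds$order[i]
      valence_sum[bonds$a1[i]] <- valence_sum[bonds$a1[i]] + o
      valence_sum[bonds$a2[i]] <- valence_sum[bonds$a2[i]] + o
      degree[bonds$a1[i]] <- degree[bonds$a1[i]] + 1L
      degree[bonds$a2[i]] <- degree[bonds$a2[i]] + 1L
    }
  }
  std_val <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
               I = 1, B = 3, Si = 4)
  nh <- pmax(0, std_val[elements] - valence_sum)
  nh[is.na(nh)] <- 0
  atoms <- data.frame(element = elements,
                      x = as.numeric(ab[, 1L]), y = as.numeric(ab[, 2L]),
                      n_h = as.numeric(nh), degree = degree,
                      stringsAsFactors = FALSE)
  list(atoms = atoms, bonds = bonds, smiles = smiles)
}

#' Test a molecule for a substructure
#'
#' SMARTS substructure presence via OpenBabel's matcher.
#'
#' @param smiles SMILES string.
#' @param smarts SMARTS pattern.
#' @return `TRUE` iff at least one match exists.
#' @export
has_substructure <- function(smiles, smarts) {
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) stop_featurize("cannot parse SMILES '", smiles, "'"))
  cnt <- suppressWarnings(
    ChemmineR::smartsSearchOB(sdf, smarts, uniqueMatches = FALSE))
  as.numeric(cnt)[1L] > 0
}

# Element display colours (RGB in [0,1]) for the structure rasteriser.
element_colour <- function(el) {
  switch(el,
         C = c(0.25, 0.25, 0.25),
         N = c(0.00, 0.00, 0.90),
         O = c(0.90, 0.00, 0.00),
         S = c(0.75, 0.70, 0.00),
         P = c(0.90, 0.45, 0.00),
         F = c(0.00, 0.65, 0.00),
         Cl = c(0.00, 0.65, 0.00),
         Br = c(0.55, 0.15, 0.05),
         I = c(0.45, 0.00, 0.55),
         c(0.60, 0.10, 0.60))
}

#' Render a molecular structure image
#'
#' Deterministic 2D structure rasteriser: depiction coordinates from
#' OpenBabel (`gen2D`) are scaled into the canvas, bonds are drawn as dark
#' lines whose thickness encodes bond order, and atoms as element-coloured
#' discs, all on a white background. Values are intensities in [0, 1].
#' Identical SMILES always yield bitwise-identical grids.
#'
#' @param smiles SMILES string.
#' @param h Image side in pixels.
#' @param channels Number of colour channels (3 = RGB).
#' @return An `h x h x channels` numeric array with values in [0, 1].
#' @export
render_image <- function(smiles, h = 32L, channels = 3L) {
  mol <- parse_smiles(smiles)
  img <- array(1, dim = c(h, h, channels))
  at <- mol$atoms
  margin <- max(2, round(0.08 * h))
  span <- max(max(at$x) - min(at$x), max(at$y) - min(at$y), 1e-6)
  scale <- (h - 2 * margin) / span
  px <- margin + (at$x - (min(at$x) + max(at$x)) / 2) * scale + (h - 2 * margin) / 2
  py <- margin + ((min(at$y) + max(at$y)) / 2 - at$y) * scale + (h - 2 * margin) / 2
  px <- pmin(pmax(px, 1), h); py <- pmin(pmax(py, 1), h)
  set_px <- function(img, xs, ys, col) {
    ok <- xs >= 1 & xs <= h & ys >= 1 & ys <= h
    xs <- round(xs[ok]); ys <- round(ys[ok])
    for (ch in seq_len(channels))
      img[cbind(ys, xs, ch)] <- col[[min(ch, 3L)]]
    img
  }
  bond_col <- c(0.1, 0.1, 0.1)
  if (nrow(mol$bonds) > 0L) {
    for (i in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]
      ord <- min(mol$bonds$order[i], 3L)
      len <- max(abs(px[b] - px[a]), abs(py[b] - py[a]), 1)
      t <- seq(0, 1, length.out = max(2L, ceiling(2 * len)))
      xs <- px[a] + t * (px[b] - px[a]); ys <- py[a] + t * (py[b] - py[a])
      img <- set_px(img, xs, ys, bond_col)
      if (ord >= 2L) {  # thicken along both axes for higher bond orders
        img <- set_px(img, xs + 1, ys, bond_col)
        img <- set_px(img, xs, ys + 1, bond_col)
      }
      if (ord >= 3L) {
        img <- set_px(img, xs - 1, ys, bond_col)
        img <- set_px(img, xs, ys - 1, bond_col)
      }
    }
  }
  r <- max(1L, round(h / 32))
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r^2, ]
  for (i in seq_len(nrow(at))) {
    col <- element_colour(at$element[i])
    img <- set_px(img, px[i] + offs$dx, py[i] + offs$dy, col)
  }
  img
}
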