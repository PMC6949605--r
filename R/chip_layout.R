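# Chip layouts: pore-patterned silicon chips scanned through the X-ray
# focus. A chip carries a rectangular grid of thinned windows separated by
# struts; each window is patterned with a hexagonal lattice of micropores
# that hold the crystal slurry.

#' Build a chip layout
#'
#' Generates the pore lattice of a fixed-target chip. Two stock designs are
#' provided: `"cxi"`, an 18 x 5 array of 1.5 x 1.5 mm windows with 15 um
#' pores on a 50 um hexagonal lattice (about 1e5 pores), and `"mfx"`, a
#' 6 x 2 array with pores spaced 100 um apart. `"custom"` takes the
#' parameters explicitly.
#'
#' @param design `"cxi"`, `"mfx"` or `"custom"`.
#' @param n_window_rows,n_window_cols window grid (custom).
#' @param window_mm window edge lengths, length-2 (custom).
#' @param strut_um strut width between windows in um.
#' @param pore_um pore diameter in um.
#' @param spacing_um hexagonal lattice constant (nearest-neighbour pore
#'   distance) in um.
#' @return an object of class `sfx_chip_layout`: window grid description and
#'   a `data.frame` `pores` with `pore_id`, `x_mm`, `y_mm`, `row`, `col`,
#'   `window_row`, `window_col`. Pores are listed in row-major scan order
#'   (by lattice row, then x), the order in which a row-by-row scan with the
#'   x axis as the fast axis visits them. Chip coordinates are mm with the
#'   origin at the chip top-left.
#' @examples
#' layout <- make_chip_layout("custom", n_window_rows = 1, n_window_cols = 1,
#'                            window_mm = c(0.5, 0.5))
#' nrow(layout$pores)
#' @export
make_chip_layout <- function(design = c("cxi", "mfx", "custom"),
                             n_window_rows = 1L, n_window_cols = 1L,
                             window_mm = c(1.5, 1.5), strut_um = 100,
                             pore_um = 15, spacing_um = 50) {
  design <- match.arg(design)
  if (design == "cxi") {
    n_window_rows <- 5L; n_window_cols <- 18L
    window_mm <- c(1.5, 1.5); strut_um <- 100
    pore_um <- 15; spacing_um <- 50
  } else if (design == "mfx") {
    n_window_rows <- 2L; n_window_cols <- 6L
    window_mm <- c(1.0, 1.5); strut_um <- 100
    pore_um <- 15; spacing_um <- 100
  }
  stopifnot(n_window_rows >= 1, n_window_cols >= 1,
            all(window_mm > 0), strut_um >= 0, pore_um > 0)
  if (spacing_um <= pore_um) {
    stop("pore spacing (", spacing_um, " um) must exceed pore diameter (",
         pore_um, " um)")
  }
  s <- spacing_um / 1000        # mm
  margin <- pore_um / 2000      # pore fully inside the window
  wx <- window_mm[1]; wy <- window_mm[2]
  pitch_x <- wx + strut_um / 1000
  pitch_y <- wy + strut_um / 1000
  dy <- s * sqrt(3) / 2

  # hexagonal lattice inside one window, relative coordinates
  ys <- seq(margin, wy - margin, by = dy)
  rows <- lapply(seq_along(ys), function(j) {
    off <- if (j %% 2 == 0) s / 2 else 0
    xs <- seq(margin + off, wx - margin, by = s)
    if (!length(xs)) return(NULL)
    data.frame(x = xs, y = ys[j], lrow = j)
  })
  cell <- do.call(rbind, rows)
  if (is.null(cell) || !nrow(cell)) stop("window too small for any pore")

  grids <- expand.grid(window_col = seq_len(n_window_cols) - 1L,
                       window_row = seq_len(n_window_rows) - 1L)
  pores <- do.call(rbind, lapply(seq_len(nrow(grids)), function(k) {
    data.frame(
      x_mm = cell$x + grids$window_col[k] * pitch_x,
      y_mm = cell$y + grids$window_row[k] * pitch_y,
      lrow = cell$lrow + grids$window_row[k] * 10000L,
      window_row = grids$window_row[k] + 1L,
      window_col = grids$window_col[k] + 1L)
  }))
  # row-major scan order: by global lattice row, then x
  ord <- order(pores$lrow, pores$x_mm)
  pores <- pores[ord, , drop = FALSE]
  row_id <- match(pores$lrow, unique(pores$lrow))
  pores$row <- row_id
  pores$col <- stats::ave(seq_len(nrow(pores)), row_id,
                          FUN = seq_along)
  pores$lrow <- NULL
  pores$pore_id <- seq_len(nrow(pores))
  rownames(pores) <- NULL
  structure(
    list(design = design,
         window_grid = c(rows = n_window_rows, cols = n_window_cols),
         window_mm = window_mm, strut_um = strut_um,
         pore_um = pore_um, spacing_um = spacing_um,
         chip_mm = c(n_window_cols * pitch_x - strut_um / 1000,
                     n_window_rows * pitch_y - strut_um / 1000),
         pores = pores[, c("pore_id", "x_mm", "y_mm", "row", "col",
                           "window_row", "window_col")]),
    class = "sfx_chip_layout")
}

#' @export
print.sfx_chip_layout <- function(x, ...) {
  cat(sprintf("<sfx_chip_layout> %s: %d x %d windows of %.2g x %.2g mm, %d pores\n",
              x$design, x$window_grid["rows"], x$window_grid["cols"],
              x$window_mm[1], x$window_mm[2], nrow(x$pores)))
  cat(sprintf("  %g um pores on a %g um hexagonal lattice\n",
              x$pore_um, x$spacing_um))
  invisible(x)
}

#' Write / read a chip-geometry definition file
#'
#' A plain-text key-value header (design parameters) followed by a TSV block
#' of pore positions, the same information the scan control software needs to
#' synchronise pore arrival with the pulse train.
#'
#' @param layout an [make_chip_layout()] object.
#' @param path output file.
#' @return `write_chip_layout` returns `path` invisibly; `read_chip_layout`
#'   returns the layout.
#' @export
write_chip_layout <- function(layout, path) {
  stopifnot(inherits(layout, "sfx_chip_layout"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    sprintf("# chip-geometry definition"),
    sprintf("design = %s", layout$design),
    sprintf("window_rows = %d", layout$window_grid["rows"]),
    sprintf("window_cols = %d", layout$window_grid["cols"]),
    sprintf("window_mm = %g %g", layout$window_mm[1], layout$window_mm[2]),
    sprintf("strut_um = %g", layout$strut_um),
    sprintf("pore_um = %g", layout$pore_um),
    sprintf("spacing_um = %g", layout$spacing_um),
    "")
  writeLines(hdr, con)
  utils::write.table(layout$pores, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_chip_layout
#' @export
read_chip_layout <- function(path) {
  lines <- readLines(path)
  kv <- grep("^[a-z_]+ = ", lines, value = TRUE)
  get <- function(key) sub(paste0("^", key, " = "), "",
                           grep(paste0("^", key, " = "), kv, value = TRUE))
  window_mm <- as.numeric(strsplit(get("window_mm"), " ")[[1]])
  make_chip_layout("custom",
                   n_window_rows = as.integer(get("window_rows")),
                   n_window_cols = as.integer(get("window_cols")),
                   window_mm = window_mm,
                   strut_um = as.numeric(get("strut_um")),
                   pore_um = as.numeric(get("pore_um")),
                   spacing_um = as.numeric(get("spacing_um")))
}

#' Detector geometry for radial analysis
#'
#' A single square panel is sufficient for azimuthally averaged background
#' analysis; only the pixel radius to scattering-vector mapping matters.
#'
#' @param n_fast,n_slow panel size in pixels.
#' @param pixel_um pixel pitch in um.
#' @param distance_mm sample-detector distance in mm. The default places the
#'   liquid-water scattering ring (q ~ 2 1/Angstrom at 7.5 keV) at about 60
#'   percent of the panel half-width.
#' @param beam_center pixel coordinates (fast, slow) of the beam centre;
#'   defaults to the panel centre.
#' @param photon_energy_kev photon energy used for the q mapping.
#' @return object of class `sfx_geometry`.
#' @export
detector_geometry <- function(n_fast = 512L, n_slow = 512L, pixel_um = 110,
                              distance_mm = 27,
                              beam_center = c(n_fast, n_slow) / 2 + 0.5,
                              photon_energy_kev = 7.5) {
  stopifnot(n_fast > 0, n_slow > 0, pixel_um > 0, distance_mm > 0,
            photon_energy_kev > 0)
  structure(list(n_fast = as.integer(n_fast), n_slow = as.integer(n_slow),
                 pixel_um = pixel_um, distance_mm = distance_mm,
                 beam_center = beam_center,
                 photon_energy_kev = photon_energy_kev),
            class = "sfx_geometry")
}

#' Scattering vector magnitude per pixel
#'
#' `q = (4 pi / lambda) sin(atan(r_mm / D) / 2)` for each pixel at radius
#' `r` from the beam centre; monotone in radius.
#'
#' @param geometry an [detector_geometry()] object.
#' @return matrix (`n_fast` x `n_slow`) of q in 1/Angstrom.
#' @export
q_map <- function(geometry) {
  stopifnot(inherits(geometry, "sfx_geometry"))
  lam <- wavelength_A(geometry$photon_energy_kev)
  px <- geometry$pixel_um / 1000  # mm
  fx <- (seq_len(geometry$n_fast) - geometry$beam_center[1]) * px
  sy <- (seq_len(geometry$n_slow) - geometry$beam_center[2]) * px
  r <- sqrt(outer(fx^2, sy^2, `+`))
  (4 * pi / lam) * sin(atan(r / geometry$distance_mm) / 2)
}
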