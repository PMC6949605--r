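# Minimal CrystFEL-stream reading and writing: enough of the dialect to
# carry per-chunk unit-cell parameters and resolution limits for unit-cell
# histogram and drift analysis. Cell lengths in streams are printed in nm;
# they are converted to Angstrom on parse.

.chunk_begin <- "----- Begin chunk -----"
.chunk_end <- "----- End chunk -----"
.crystal_begin <- "--- Begin crystal"
.crystal_end <- "--- End crystal"

#' Write a synthetic CrystFEL-style stream file
#'
#' Emits one chunk per row of `cells`, each with a crystal block holding a
#' `Cell parameters` line (nm / degrees, the stream convention) and a
#' `diffraction_resolution_limit` line. Round-trips losslessly through
#' [parse_stream()] to the printed precision (1e-5 nm, i.e. 1e-4 Angstrom,
#' and 0.01 degrees).
#'
#' @param cells `data.frame` with columns `a`, `b`, `c` (Angstrom), `al`,
#'   `be`, `ga` (degrees) and optionally `resolution_limit` (Angstrom).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stream_fixture <- function(cells, path) {
  stopifnot(is.data.frame(cells))
  if (nrow(cells) > 0) {
    stopifnot(all(c("a", "b", "c", "al", "be", "ga") %in% names(cells)),
              all(cells[, c("a", "b", "c")] > 0),
              all(cells[, c("al", "be", "ga")] > 0),
              all(cells[, c("al", "be", "ga")] < 180))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("CrystFEL stream format 2.3",
               "Generated by sfxchip (synthetic fixture)"), con)
  for (i in seq_len(nrow(cells))) {
    res <- if ("resolution_limit" %in% names(cells) &&
               is.finite(cells$resolution_limit[i])) {
      cells$resolution_limit[i]
    } else NA_real_
    lines <- c(
      .chunk_begin,
      sprintf("Image filename: synthetic_%06d.h5", i),
      "indexed_by = mosflm-nolatt-nocell",
      .crystal_begin,
      sprintf("Cell parameters %.5f %.5f %.5f nm, %.2f %.2f %.2f deg",
              cells$a[i] / 10, cells$b[i] / 10, cells$c[i] / 10,
              cells$al[i], cells$be[i], cells$ga[i]),
      if (!is.na(res)) {
        sprintf("diffraction_resolution_limit = %.2f nm^-1 or %.2f A",
                10 / res, res)
      },
      .crystal_end,
      .chunk_end)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Parse unit cells from a CrystFEL-style stream
#'
#' Extracts one record per indexed chunk: the cell parameters (converted
#' from nm to Angstrom), the resolution limit when present, the chunk index,
#' and the triclinic cell volume. Unindexed chunks (no `Cell parameters`
#' line) are skipped; malformed cell lines are skipped with a warning, or
#' raise an error in strict mode.
#'
#' @param path stream file path.
#' @param strict error (rather than warn) on malformed cell lines.
#' @return `data.frame` with columns `chunk`, `a`, `b`, `c` (Angstrom),
#'   `al`, `be`, `ga` (degrees), `resolution_limit` (Angstrom, `NA` when
#'   absent), `cell_volume` (Angstrom^3).
#' @export
parse_stream <- function(path, strict = FALSE) {
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == .chunk_begin)
  ends <- which(lines == .chunk_end)
  empty <- data.frame(chunk = integer(), a = numeric(), b = numeric(),
                      c = numeric(), al = numeric(), be = numeric(),
                      ga = numeric(), resolution_limit = numeric(),
                      cell_volume = numeric())
  if (!length(begins)) return(empty)
  if (length(ends) < length(begins)) {
    msg <- "stream has an unterminated chunk"
    if (strict) stop(msg) else warning(msg)
  }
  end_for <- ends[findInterval(begins, ends) + 1L]
  recs <- list()
  for (k in seq_along(begins)) {
    if (is.na(end_for[k])) next
    block <- lines[begins[k]:end_for[k]]
    cl <- grep("^Cell parameters", block, value = TRUE)
    if (!length(cl)) next  # unindexed chunk
    nums <- regmatches(cl[1], gregexpr("-?[0-9]+\\.?[0-9]*", cl[1]))[[1]]
    if (length(nums) < 6) {
      msg <- paste0("malformed cell line in chunk ", k, ": ", cl[1])
      if (strict) stop(msg)
      warning(msg)
      next
    }
    v <- as.numeric(nums[1:6])
    a <- v[1] * 10; b <- v[2] * 10; cc <- v[3] * 10  # nm -> Angstrom
    if (any(!is.finite(c(a, b, cc))) || any(c(a, b, cc) <= 0) ||
        any(v[4:6] <= 0) || any(v[4:6] >= 180)) {
      msg <- paste0("invalid cell values in chunk ", k)
      if (strict) stop(msg)
      warning(msg)
      next
    }
    rl <- grep("^diffraction_resolution_limit", block, value = TRUE)
    res <- NA_real_
    if (length(rl)) {
      m <- regmatches(rl[1],
                      regexec("or ([0-9]+\\.?[0-9]*) A", rl[1]))[[1]]
      if (length(m) == 2) res <- as.numeric(m[2])
    }
    recs[[length(recs) + 1L]] <- data.frame(
      chunk = k, a = a, b = b, c = cc,
      al = v[4], be = v[5], ga = v[6], resolution_limit = res)
  }
  if (!length(recs)) return(empty)
  out <- do.call(rbind, recs)
  out$cell_volume <- cell_volume(out$a, out$b, out$c, out$al, out$be, out$ga)
  out
}

#' Triclinic unit-cell volume
#'
#' `V = abc sqrt(1 - cos^2 al - cos^2 be - cos^2 ga
#'               + 2 cos al cos be cos ga)`.
#'
#' @param a,b,c cell lengths (Angstrom).
#' @param al,be,ga cell angles (degrees), each in (0, 180).
#' @return volume in Angstrom^3 (vectorised).
#' @export
cell_volume <- function(a, b, c, al, be, ga) {
  stopifnot(all(a > 0), all(b > 0), all(c > 0),
            all(al > 0 & al < 180), all(be > 0 & be < 180),
            all(ga > 0 & ga < 180))
  ca <- cospi(al / 180); cb <- cospi(be / 180); cg <- cospi(ga / 180)
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  a * b * c * sqrt(pmax(arg, 0))
}

#' Binned unit-cell summary and drift estimate
#'
#' Summarises cell parameters, cell volume and resolution limit in
#' consecutive bins of chunk order (a proxy for time), and fits a linear
#' trend of cell volume and resolution against chunk index. A constant cell
#' yields a slope of exactly zero; dehydration shows up as a negative
#' volume slope several standard errors from zero.
#'
#' @param records output of [parse_stream()].
#' @param time_bins number of equal-count bins over chunk order.
#' @return list with `bins` (`data.frame` of per-bin mean/sd for each
#'   parameter; sd is `NA` in bins with fewer than 2 records), and `trend`
#'   (`data.frame` with `quantity`, `slope`, `slope_se`, per chunk index).
#' @export
cell_summary <- function(records, time_bins = 10) {
  stopifnot(is.data.frame(records), nrow(records) >= 1, time_bins >= 1)
  ord <- order(records$chunk)
  rec <- records[ord, , drop = FALSE]
  n <- nrow(rec)
  bin <- ceiling(seq_len(n) / ceiling(n / time_bins))
  qty <- c("a", "b", "c", "al", "be", "ga", "cell_volume",
           "resolution_limit")
  bins <- do.call(rbind, lapply(sort(unique(bin)), function(bk) {
    sub <- rec[bin == bk, , drop = FALSE]
    row <- data.frame(bin = bk, n = nrow(sub))
    for (q in qty) {
      v <- sub[[q]]
      row[[paste0(q, "_mean")]] <- mean(v, na.rm = TRUE)
      row[[paste0(q, "_sd")]] <- if (sum(is.finite(v)) >= 2) {
        stats::sd(v, na.rm = TRUE)
      } else NA_real_
    }
    row
  }))
  trend <- do.call(rbind, lapply(c("cell_volume", "resolution_limit"),
                                 function(q) {
    v <- rec[[q]]
    ok <- is.finite(v)
    if (sum(ok) < 3 || stats::var(v[ok]) == 0) {
      return(data.frame(quantity = q,
                        slope = if (sum(ok) >= 2) 0 else NA_real_,
                        slope_se = NA_real_))
    }
    fit <- stats::lm(v[ok] ~ rec$chunk[ok])
    cf <- summary(fit)$coefficients
    data.frame(quantity = q, slope = cf[2, 1], slope_se = cf[2, 2])
  }))
  list(bins = bins, trend = trend)
}
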