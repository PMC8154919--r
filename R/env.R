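#' Regular environmental grid
#'
#' A minimal raster-like container: a values matrix whose first row is the
#' northernmost, plus the ESRI ASCII header fields (lower-left corner,
#' square cell size, nodata value). Cell centers are at
#' `x = xll + (col - 0.5) * cellsize`, `y = yll + (nrow - row + 0.5) *
#' cellsize`.
#'
#' @param values numeric matrix (row 1 = north).
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param cellsize cell edge length, in the same units as the coordinates.
#' @param nodata value standing for missing cells in files.
#' @return list of class `env_grid`.
#' @export
envGrid <- function(values, xll = 0, yll = 0, cellsize = 1,
                    nodata = -9999) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata),
            class = "env_grid")
}

#' Read an ESRI ASCII raster
#'
#' Six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by whitespace-separated rows, north first.
#'
#' @param path file path.
#' @return an [envGrid()] object; nodata cells become `NA`.
#' @export
readEsriAscii <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "[ \t]+")
  key <- tolower(vapply(kv, `[`, "", 1))
  val <- as.numeric(vapply(kv, `[`, "", 2))
  names(val) <- key
  ncols <- as.integer(val[["ncols"]]); nrows <- as.integer(val[["nrows"]])
  body <- scan(path, skip = 6, quiet = TRUE)
  if (length(body) != ncols * nrows)
    stop("raster body does not match ncols x nrows")
  m <- matrix(body, nrows, ncols, byrow = TRUE)
  nodata <- val[["nodata_value"]]
  m[m == nodata] <- NA
  envGrid(m, xll = val[["xllcorner"]], yll = val[["yllcorner"]],
          cellsize = val[["cellsize"]], nodata = nodata)
}

#' Write an ESRI ASCII raster
#'
#' @param grid an [envGrid()] object.
#' @param path output path.
#' @export
writeEsriAscii <- function(grid, path) {
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
               paste("xllcorner", grid$xll), paste("yllcorner", grid$yll),
               paste("cellsize", grid$cellsize),
               paste("NODATA_value", grid$nodata)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(m[i, ], collapse = " "), con)
  invisible(path)
}

#' Extract grid values at points
#'
#' Nearest-cell (containing-cell) lookup, no interpolation. Points outside
#' the grid bounds get `NA` with a warning.
#'
#' @param grid an [envGrid()] object.
#' @param x,y point coordinates (e.g. longitude and latitude), equal
#'   length.
#' @return numeric vector of cell values.
#' @export
extractAtPoints <- function(grid, x, y) {
  stopifnot(length(x) == length(y))
  if (length(grid$values) == 0) stop("empty grid")
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((x - grid$xll) / grid$cellsize) + 1
  rowFromBottom <- floor((y - grid$yll) / grid$cellsize) + 1
  row <- nr - rowFromBottom + 1
  out <- rep(NA_real_, length(x))
  inside <- col >= 1 & col <= nc & row >= 1 & row <= nr
  if (any(!inside))
    warning(sum(!inside), " point(s) outside the grid bounds; value absent")
  out[inside] <- grid$values[cbind(row[inside], col[inside])]
  out
}

#' Terrain slope from an elevation grid
#'
#' Horn's eight-neighbor finite-difference gradient; slope returned in
#' degrees. Border cells (and cells with a missing neighbor) are `NA`.
#' Elevation and cell size must share the same length unit.
#'
#' @param grid an [envGrid()] elevation grid, at least 3 x 3.
#' @return an [envGrid()] of slopes (degrees).
#' @export
slopeFromElevation <- function(grid) {
  z <- grid$values
  if (nrow(z) < 3 || ncol(z) < 3) stop("elevation grid must be at least 3 x 3")
  cs <- grid$cellsize
  nr <- nrow(z); nc <- ncol(z)
  slope <- matrix(NA_real_, nr, nc)
  for (i in 2:(nr - 1)) {
    for (j in 2:(nc - 1)) {
      a <- z[i - 1, j - 1]; b <- z[i - 1, j]; c <- z[i - 1, j + 1]
      d <- z[i, j - 1];                        f <- z[i, j + 1]
      g <- z[i + 1, j - 1]; h <- z[i + 1, j]; k <- z[i + 1, j + 1]
      dzdx <- ((c + 2 * f + k) - (a + 2 * d + g)) / (8 * cs)
      dzdy <- ((g + 2 * h + k) - (a + 2 * b + c)) / (8 * cs)
      slope[i, j] <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
    }
  }
  envGrid(slope, xll = grid$xll, yll = grid$yll, cellsize = cs,
          nodata = grid$nodata)
}

#' Iterative reduction of correlated environmental variables
#'
#' Computes pairwise Pearson correlations over the sampling units and, while
#' the maximum squared correlation (or absolute correlation, with
#' `corOn = "r"`) is at or above the threshold, removes one variable of the
#' most correlated pair, chosen by a seeded coin flip. Returns the retained
#' set and a map from every removed variable to its retained proxy (the
#' surviving end of the chain of removals).
#'
#' @param vars data.frame or matrix, units x variables, numeric.
#' @param threshold reduction threshold (default 0.7, applied to r^2).
#' @param corOn `"r2"` (default) to threshold squared correlations or
#'   `"r"` for absolute correlations.
#' @param seed integer seed for the removal coin flips.
#' @return list with `retained` (character vector), `excluded`
#'   (data.frame `removed`, `proxy`, `r` with the correlation between them)
#'   and `maxR2` among retained variables.
#' @export
reduceCorrelated <- function(vars, threshold = 0.7, corOn = c("r2", "r"),
                             seed = 1L) {
  corOn <- match.arg(corOn)
  vars <- as.data.frame(vars)
  if (ncol(vars) < 2) stop("need at least two variables")
  complete <- stats::complete.cases(vars)
  if (sum(complete) < 3) stop("need at least three complete units")
  vars <- vars[complete, , drop = FALSE]
  set.seed(seed)
  keep <- names(vars)
  removedTo <- character(0)
  repeat {
    cm <- suppressWarnings(stats::cor(vars[, keep, drop = FALSE]))
    diag(cm) <- 0
    stat <- if (corOn == "r2") cm^2 else abs(cm)
    mx <- max(stat, na.rm = TRUE)
    if (mx < threshold) break
    pair <- which(stat == mx, arr.ind = TRUE)[1, ]
    v <- keep[pair][sample.int(2, 1)]
    other <- setdiff(keep[pair], v)
    removedTo[v] <- other
    keep <- setdiff(keep, v)
    if (length(keep) < 2) break
  }
  # resolve chains: a removed variable's proxy may itself have been removed
  resolve <- function(v) {
    while (v %in% names(removedTo)) v <- removedTo[[v]]
    v
  }
  excluded <- data.frame(
    removed = names(removedTo),
    proxy = vapply(names(removedTo), resolve, ""),
    stringsAsFactors = FALSE, row.names = NULL)
  excluded$r <- mapply(function(a, b) stats::cor(vars[[a]], vars[[b]]),
                       excluded$removed, excluded$proxy)
  cmK <- if (length(keep) >= 2) {
    ck <- suppressWarnings(stats::cor(vars[, keep, drop = FALSE]))
    diag(ck) <- 0
    max(ck^2, na.rm = TRUE)
  } else 0
  list(retained = keep, excluded = excluded, maxR2 = cmK)
}

#' Long-format environmental table helpers
#'
#' `envValue()` pulls one (id, variable, epoch) cell out of a long
#' environmental table (`breed`/`id`, `variable`, `epoch`, `value`);
#' `envDelta()` returns future minus current for each id.
#'
#' @param env long environmental table.
#' @param variable variable name.
#' @param epoch `"current"` or `"future"`.
#' @return named numeric vector (by id).
#' @export
envValue <- function(env, variable, epoch = "current") {
  idCol <- intersect(c("breed", "id"), names(env))[1]
  sub <- env[env$variable == variable & env$epoch == epoch, ]
  stats::setNames(sub$value, sub[[idCol]])
}

#' @rdname envValue
#' @export
envDelta <- function(env, variable) {
  cur <- envValue(env, variable, "current")
  fut <- envValue(env, variable, "future")
  fut[names(cur)] - cur
}
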