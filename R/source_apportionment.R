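#' Classify emission sources by the toluene/benzene ratio
#'
#' The T/B concentration ratio is a widely used diagnostic of BTEX origin:
#' ratios below 1 point to biomass/biofuel/coal burning, ratios of roughly
#' 1-10 to vehicle exhaust, and larger ratios to industrial processes and
#' solvent use. Published bands overlap (industrial sources are often quoted
#' simply as ">1"); this classifier uses the disjoint bins
#' `< 1` / `[1, 10]` / `> 10` so the label is deterministic, and always
#' returns the raw ratio so callers can re-bin. The label is invariant to a
#' common rescaling of both concentrations.
#'
#' @param toluene,benzene Concentrations (ug/m3), vectorised; benzene must
#'   be > 0.
#' @return Data frame with columns `ratio` and `label`
#'   (`bm_bf_cb` | `traffic` | `industrial_solvent`).
#' @examples
#' tb_ratio_classify(c(0.5, 5, 30), c(1, 1, 1))
#' @export
tb_ratio_classify <- function(toluene, benzene) {
  stopifnot(is.numeric(toluene), is.numeric(benzene),
            length(toluene) == length(benzene))
  if (any(benzene <= 0)) {
    stop("benzene concentrations must be > 0 to form the T/B ratio",
         call. = FALSE)
  }
  if (any(toluene < 0)) stop("toluene concentrations must be >= 0",
                             call. = FALSE)
  ratio <- toluene / benzene
  label <- ifelse(ratio < 1, "bm_bf_cb",
                  ifelse(ratio <= 10, "traffic", "industrial_solvent"))
  data.frame(ratio = ratio, label = label, stringsAsFactors = FALSE)
}

#' Ternary composition of benzene, toluene and ethylbenzene
#'
#' Normalises the three concentrations by their sum, giving the coordinates
#' used to place a sample on a B-T-E ternary source diagram. Scale-invariant.
#'
#' @param b,t,e Concentrations (same units), all >= 0, sum > 0. Vectorised.
#' @return Data frame with columns `b_frac`, `t_frac`, `e_frac`, each row
#'   summing to 1.
#' @export
ternary_coords <- function(b, t, e) {
  stopifnot(length(b) == length(t), length(t) == length(e))
  if (any(c(b, t, e) < 0)) stop("concentrations must be >= 0", call. = FALSE)
  s <- b + t + e
  if (any(s <= 0)) {
    stop("b + t + e must be > 0 for every sample", call. = FALSE)
  }
  data.frame(b_frac = b / s, t_frac = t / s, e_frac = e / s)
}

# Project a ternary composition (b, t, e) onto the plane: the standard
# equilateral-triangle embedding with the benzene vertex at the origin.
ternary_to_xy <- function(b_frac, t_frac, e_frac) {
  cbind(x = t_frac + 0.5 * e_frac, y = (sqrt(3) / 2) * e_frac)
}

# Winding-number point-in-polygon test, inclusive on edges and vertices.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  on_edge <- function() {
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      cross <- (vx[j] - vx[i]) * (py - vy[i]) - (px - vx[i]) * (vy[j] - vy[i])
      if (abs(cross) < 1e-12 &&
          px >= min(vx[i], vx[j]) - 1e-12 &&
          px <= max(vx[i], vx[j]) + 1e-12 &&
          py >= min(vy[i], vy[j]) - 1e-12 &&
          py <= max(vy[i], vy[j]) + 1e-12) {
        return(TRUE)
      }
    }
    FALSE
  }
  if (on_edge()) return(TRUE)
  wn <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (vy[i] <= py) {
      if (vy[j] > py &&
          (vx[j] - vx[i]) * (py - vy[i]) - (px - vx[i]) * (vy[j] - vy[i]) > 0)
        wn <- wn + 1L
    } else {
      if (vy[j] <= py &&
          (vx[j] - vx[i]) * (py - vy[i]) - (px - vx[i]) * (vy[j] - vy[i]) < 0)
        wn <- wn - 1L
    }
  }
  wn != 0L
}

#' Source regions on the B-T-E ternary diagram
#'
#' `source_region()` builds one region from a label and a matrix (or list) of
#' ternary vertices; `load_source_regions()` reads a JSON region file of the
#' form `[{"label": ..., "vertices": [[b,t,e], ...]}, ...]`;
#' `default_source_regions()` loads the synthetic approximate profiles
#' shipped with the package (placeholders for source fingerprints that must
#' be measured or taken from a source-profile library — edit the JSON for
#' real use).
#'
#' @param label Region label, e.g. `"bm_bf_cb"`, `"traffic"`,
#'   `"industrial_solvent"` or any custom string.
#' @param vertices Numeric matrix with >= 3 rows and columns (b, t, e); each
#'   row is normalised to a composition.
#' @param path Path to a region JSON file.
#' @return A `source_region`, or a list of them.
#' @export
source_region <- function(label, vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L || ncol(vertices) != 3L) {
    stop("a source region needs >= 3 ternary vertices (columns b, t, e)",
         call. = FALSE)
  }
  comp <- ternary_coords(vertices[, 1], vertices[, 2], vertices[, 3])
  xy <- ternary_to_xy(comp$b_frac, comp$t_frac, comp$e_frac)
  # shoelace area; a degenerate polygon cannot classify anything
  x <- xy[, 1]; y <- xy[, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  if (area < 1e-12) {
    stop("degenerate (zero-area) polygon for region '", label, "'",
         call. = FALSE)
  }
  structure(list(label = label, vertices = as.matrix(comp), xy = xy),
            class = "source_region")
}

#' @rdname source_region
#' @export
load_source_regions <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(spec, function(r) {
    v <- do.call(rbind, lapply(r$vertices, unlist))
    source_region(r$label, v)
  })
}

#' @rdname source_region
#' @export
default_source_regions <- function() {
  load_source_regions(system.file("extdata", "source_regions_synthetic.json",
                                  package = "btexrisk", mustWork = TRUE))
}

#' Classify a ternary composition against source regions
#'
#' Point-in-polygon test in the 2-D ternary embedding, inclusive on region
#' boundaries (a point on a shared edge belongs to both regions). Regions
#' may overlap; all containing regions are returned. An empty result means
#' the composition matches no configured source profile.
#'
#' @param comp A one-row data frame (or list) with `b_frac`, `t_frac`,
#'   `e_frac`, e.g. one row of [ternary_coords()].
#' @param regions List of [source_region] objects.
#' @return Character vector of matching labels (possibly empty).
#' @export
classify_composition <- function(comp, regions) {
  if (!length(regions)) stop("'regions' must be non-empty", call. = FALSE)
  p <- ternary_to_xy(comp$b_frac, comp$t_frac, comp$e_frac)
  hits <- vapply(regions, function(r) {
    point_in_polygon(p[1], p[2], r$xy[, 1], r$xy[, 2])
  }, logical(1))
  vapply(regions[hits], `[[`, character(1), "label")
}

#' Spearman correlation between co-emitted species
#'
#' Rank correlation of benzene and toluene concentrations across sampling
#' sites: strongly correlated species point to a common emission source.
#' Rho is the Pearson correlation of average ranks; the two-sided p-value
#' uses the t approximation `t = rho sqrt((n-2)/(1-rho^2))` on n - 2 degrees
#' of freedom. A constant input vector has no rank ordering; rho is reported
#' as 0 with `flag = TRUE`.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return List with `rho`, `p_value`, `n`, `flag`.
#' @export
co_emission_correlation <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(rho = 0, p_value = NA_real_, n = n, flag = TRUE))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p_value = p, n = n, flag = FALSE)
}
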