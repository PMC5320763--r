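#' Configuration for synthetic landscapes and observation sets
#'
#' Describes a synthetic study system with the statistical structure of a
#' clonal-shrub mapping study: categorical land-cover/soil mosaics with
#' spatially autocorrelated patches, a patchy presence process whose
#' intensity depends on favoured land-cover categories, coverage values
#' concentrated at zero with a continuous right tail up to `max_coverage`,
#' and walking-track point chains that oversample the landscape (thinning
#' test material). All outputs are deterministic under `seed`.
#'
#' @param n_rows,n_cols landscape extent in cells.
#' @param cellsize cell size in metres (10 m, the feature-layer resolution).
#' @param categories named list giving the number of categories per
#'   categorical layer.
#' @param mixing named list of category mixing proportions per layer
#'   (default uniform).
#' @param n_landscape_patches region-growing seeds per layer (patchiness).
#' @param favour_categories land-cover codes favoured by the species.
#' @param favour_strength relative intensity of presence-patch seeding in
#'   favoured categories (`Inf` = exclusive).
#' @param n_presence_patches number of clonal presence patches.
#' @param patch_radius patch radius in metres.
#' @param points_per_patch expected observation points per patch.
#' @param zero_mass point mass at zero of the coverage distribution of
#'   survey points (zero-inflation share).
#' @param max_coverage upper end of the continuous coverage tail (0.9).
#' @param coverage_shape1,coverage_shape2 beta shape parameters of the
#'   positive coverage tail (right-skewed by default).
#' @param n_tracks,track_steps,track_step_len simulated walking tracks:
#'   number of tracks, steps per track and step length in metres.
#' @param seed RNG seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_rows = 100, n_cols = 100, cellsize = 10,
                         categories = list(landcover = 6, soil = 5),
                         mixing = NULL,
                         n_landscape_patches = 40,
                         favour_categories = 1,
                         favour_strength = 20,
                         n_presence_patches = 12,
                         patch_radius = 60,
                         points_per_patch = 25,
                         zero_mass = 0.6,
                         max_coverage = 0.9,
                         coverage_shape1 = 0.8,
                         coverage_shape2 = 2.5,
                         n_tracks = 4, track_steps = 300, track_step_len = 12,
                         seed = 1) {
  stopifnot(n_rows >= 1, n_cols >= 1, cellsize > 0,
            zero_mass >= 0, zero_mass <= 1, max_coverage <= 1)
  structure(as.list(environment()), class = "synth_config")
}

# region-growing categorical mosaic: category codes spread outward from
# randomly placed seeds, giving spatially autocorrelated patches.
grow_mosaic <- function(n_rows, n_cols, n_cat, n_seeds, mixing = NULL) {
  m <- matrix(NA_integer_, n_rows, n_cols)
  if (is.null(mixing)) mixing <- rep(1 / n_cat, n_cat)
  n_seeds <- min(n_seeds, n_rows * n_cols)
  cells <- sample.int(n_rows * n_cols, n_seeds)
  m[cells] <- sample.int(n_cat, n_seeds, replace = TRUE, prob = mixing)
  shift <- function(mm, dr, dc) {
    out <- matrix(NA_integer_, n_rows, n_cols)
    rs <- seq_len(n_rows) - dr; cs <- seq_len(n_cols) - dc
    ok_r <- rs >= 1 & rs <= n_rows; ok_c <- cs >= 1 & cs <= n_cols
    out[ok_r, ok_c] <- mm[rs[ok_r], cs[ok_c]]
    out
  }
  while (anyNA(m)) {
    dirs <- sample(4)  # random direction priority each sweep
    neigh <- list(shift(m, 1, 0), shift(m, -1, 0),
                  shift(m, 0, 1), shift(m, 0, -1))[dirs]
    for (nb in neigh) {
      fill <- is.na(m) & !is.na(nb)
      m[fill] <- nb[fill]
    }
  }
  m
}

#' Generate a synthetic landscape
#'
#' One categorical [grid_raster] per layer in `cfg$categories`, built by
#' region-growing from random seeds so categories form contiguous patches.
#'
#' @param cfg a [synth_config].
#' @return Named list of categorical [grid_raster]s.
#' @export
generate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_rng_seed(cfg$seed, {
    out <- list()
    for (nm in names(cfg$categories)) {
      m <- grow_mosaic(cfg$n_rows, cfg$n_cols, cfg$categories[[nm]],
                       cfg$n_landscape_patches,
                       mixing = cfg$mixing[[nm]])
      out[[nm]] <- grid_raster(m, 0, 0, cfg$cellsize, categorical = TRUE)
    }
    out
  })
}

# zero-inflated coverage draw for survey points
draw_coverage <- function(n, cfg) {
  z <- stats::runif(n) < cfg$zero_mass
  cov <- numeric(n)
  pos <- !z
  if (any(pos))
    cov[pos] <- cfg$max_coverage *
      stats::rbeta(sum(pos), cfg$coverage_shape1, cfg$coverage_shape2)
  cov
}

#' Generate synthetic observation records
#'
#' Seeds clonal presence patches preferentially in the favoured land-cover
#' categories, scatters survey points around the patch centres with
#' zero-inflated coverage (point mass at zero, right-skewed continuous tail
#' to `max_coverage`), and simulates walking-track point chains (dense,
#' regularly spaced, all zero coverage) across the landscape. Ground truth
#' (patch centres, the truly occupied cell mask and the generating
#' configuration) is returned alongside so recovery tests never compare
#' against unknowns.
#'
#' @param landscape layer list from [generate_landscape()].
#' @param cfg the [synth_config] used to build the landscape.
#' @return List with `records` (data.frame `x`, `y`, `coverage`, `source`)
#'   and `truth` (list: `patch_centers`, `occupied`, `favour_categories`,
#'   `config`).
#' @export
generate_observations <- function(landscape, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  lc <- landscape[[1]]
  xmax <- cfg$n_cols * cfg$cellsize
  ymax <- cfg$n_rows * cfg$cellsize
  with_rng_seed(cfg$seed + 1L, {
    # presence patch centres, favouring chosen land-cover categories
    fav <- lc$values %in% cfg$favour_categories
    wt <- if (is.infinite(cfg$favour_strength)) as.numeric(fav)
    else ifelse(fav, cfg$favour_strength, 1)
    centers <- NULL
    if (cfg$n_presence_patches > 0) {
      if (sum(wt) == 0) stopf("no cell available for presence patches")
      cells <- sample.int(length(wt), cfg$n_presence_patches,
                          replace = FALSE, prob = wt)
      rc <- cbind((cells - 1) %% nrow(lc$values) + 1,
                  (cells - 1) %/% nrow(lc$values) + 1)
      centers <- cell_center(lc, rc[, 1], rc[, 2])
    }
    pts <- list()
    if (!is.null(centers)) {
      for (p in seq_len(nrow(centers))) {
        np <- stats::rpois(1, cfg$points_per_patch)
        if (np == 0) next
        ang <- stats::runif(np, 0, 2 * pi)
        rad <- cfg$patch_radius * sqrt(stats::runif(np))
        px <- pmin(pmax(centers[p, 1] + rad * cos(ang), 0.5), xmax - 0.5)
        py <- pmin(pmax(centers[p, 2] + rad * sin(ang), 0.5), ymax - 0.5)
        pts[[p]] <- data.frame(x = px, y = py,
                               coverage = draw_coverage(np, cfg),
                               source = "active")
      }
    }
    active <- if (length(pts) > 0) do.call(rbind, pts)
    else data.frame(x = numeric(0), y = numeric(0), coverage = numeric(0),
                    source = character(0))
    # walking tracks: correlated random walks with regular step length
    tracks <- list()
    if (cfg$n_tracks > 0) {
      for (t in seq_len(cfg$n_tracks)) {
        x0 <- stats::runif(1, 0, xmax); y0 <- stats::runif(1, 0, ymax)
        heading <- stats::runif(1, 0, 2 * pi)
        dx <- dy <- numeric(cfg$track_steps)
        for (s in seq_len(cfg$track_steps)) {
          heading <- heading + stats::rnorm(1, 0, 0.35)
          dx[s] <- cos(heading); dy[s] <- sin(heading)
        }
        tx <- x0 + cumsum(dx) * cfg$track_step_len
        ty <- y0 + cumsum(dy) * cfg$track_step_len
        ok <- tx >= 0 & tx < xmax & ty >= 0 & ty < ymax
        tracks[[t]] <- data.frame(x = tx[ok], y = ty[ok], coverage = 0,
                                  source = "track")
      }
    }
    track <- if (length(tracks) > 0) do.call(rbind, tracks)
    else data.frame(x = numeric(0), y = numeric(0), coverage = numeric(0),
                    source = character(0))
    records <- rbind(active, track)
    rownames(records) <- NULL
    # truly occupied cells: within patch_radius of a patch centre
    occupied <- matrix(FALSE, cfg$n_rows, cfg$n_cols)
    if (!is.null(centers)) {
      idx <- cbind(rep(seq_len(cfg$n_rows), times = cfg$n_cols),
                   rep(seq_len(cfg$n_cols), each = cfg$n_rows))
      cc <- cell_center(lc, idx[, 1], idx[, 2])
      for (p in seq_len(nrow(centers))) {
        d2 <- (cc[, 1] - centers[p, 1])^2 + (cc[, 2] - centers[p, 2])^2
        occupied[idx[d2 <= cfg$patch_radius^2, , drop = FALSE]] <- TRUE
      }
    }
    list(records = records,
         truth = list(patch_centers = centers, occupied = occupied,
                      favour_categories = cfg$favour_categories,
                      config = cfg))
  })
}
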