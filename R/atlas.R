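# The 34 Desikan parcellation names per hemisphere.
desikan_names <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
  "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
  "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
  "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
  "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
  "precentral", "precuneus", "rostralanteriorcingulate",
  "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
  "superiortemporal", "supramarginal", "temporalpole", "transversetemporal"
)

#' Synthetic 68-region atlas on the unit sphere
#'
#' Places 34 Desikan-style region centroids per hemisphere on one unit
#' sphere: each hemisphere gets a quasi-uniform Fibonacci lattice restricted
#' to its own longitude half (`[0, pi)` for left, `[pi, 2*pi)` for right),
#' plus a small seeded jitter so centroid layouts differ across seeds while
#' staying well separated. This is a synthetic stand-in for real Desikan
#' centroids; names carry `_lh` / `_rh` suffixes.
#'
#' @param seed Integer seed; identical seeds give identical atlases.
#' @return A tibble with columns `region`, `hemisphere` (`"L"`/`"R"`),
#'   `colatitude`, `longitude` (radians).
#' @export
make_atlas <- function(seed = 1L) {
  n_hemi <- length(desikan_names)
  golden <- pi * (3 - sqrt(5))
  # interleave the two hemisphere lattices in colatitude (quarter-step
  # offsets) and keep clear of the poles so left/right rings never collide
  one_hemi <- function(hemi, rng) {
    i <- seq_len(n_hemi)
    off <- if (hemi == "L") 0.3 else 0.7
    z <- 0.92 * (1 - 2 * (i - off) / n_hemi)
    colat <- acos(pmin(1, pmax(-1, z))) + rng$jit1
    lon <- 0.06 + 0.96 * (((i - 1) * golden) %% pi) + rng$jit2
    lon <- lon %% pi + if (hemi == "R") pi else 0
    tibble::tibble(
      region = paste0(desikan_names, if (hemi == "L") "_lh" else "_rh"),
      hemisphere = hemi,
      colatitude = pmin(pi - 0.02, pmax(0.02, colat)),
      longitude = lon
    )
  }
  withr_seed(seed, {
    jl <- list(jit1 = stats::rnorm(n_hemi, 0, 0.01),
               jit2 = stats::rnorm(n_hemi, 0, 0.01))
    jr <- list(jit1 = stats::rnorm(n_hemi, 0, 0.01),
               jit2 = stats::rnorm(n_hemi, 0, 0.01))
    dplyr::bind_rows(one_hemi("L", jl), one_hemi("R", jr))
  })
}

# Run code with a local RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Read / write a region atlas
#'
#' Delimited-text atlas I/O with columns `region`, `hemisphere`,
#' `colatitude`, `longitude`.
#'
#' @param path File path (tab-separated).
#' @param atlas Atlas tibble, for writing.
#' @return `read_atlas()` returns the atlas tibble.
#' @export
read_atlas <- function(path) {
  at <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("region", "hemisphere", "colatitude", "longitude")
  if (!all(need %in% names(at))) {
    stop("atlas file must have columns: ", paste(need, collapse = ", "))
  }
  validate_atlas(at)
  at
}

#' @rdname read_atlas
#' @export
write_atlas <- function(atlas, path) {
  validate_atlas(atlas)
  readr::write_tsv(atlas, path)
  invisible(path)
}

validate_atlas <- function(atlas) {
  if (anyDuplicated(atlas$region)) stop("atlas region names must be unique")
  if (any(!is.finite(atlas$colatitude)) || any(!is.finite(atlas$longitude))) {
    stop("atlas centroids must be finite")
  }
  xyz <- sphere_to_xyz(atlas)
  if (min(stats::dist(xyz)) < 1e-9) stop("atlas centroids must be distinct")
  invisible(atlas)
}
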