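# Seeded synthetic IHC image generator with analytic ground truth.
#
# Images are forward-rendered from per-region stain concentration fields
# through the same Beer-Lambert mixing model the separation module
# inverts: RGB = background * 10^(-M %*% c), quantized to 8 bits, plus
# optional Gaussian channel noise. Because concentration ranges are
# calibrated against the configured stain matrix (not hard-coded), the
# generator stays in-zone when the matrix preset changes.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' DAB concentration range that renders inside a scoring zone
#'
#' Inverts the render equation `I = 255 * 10^(-c)` for the DAB intensity
#' interval of a zone, shrunk by a safety margin so that 8-bit
#' quantization through the full render/de-convolve round trip cannot
#' push a pixel across a zone boundary.
#'
#' @param zone Integer grade zone 0-3.
#' @param zones The four upper zone boundaries.
#' @param margin Intensity units trimmed off each zone edge (default 3).
#' @param darkest Lowest intensity used for the open-ended 3+ zone
#'   (default 15); a DAB intensity of 0 would need infinite concentration.
#' @return `c(lo, hi)` concentration bounds.
#' @export
zone_concentration_range <- function(zone, zones = c(60L, 120L, 170L, 230L),
                                     margin = 3, darkest = 15) {
  stopifnot(zone %in% 0:3)
  lower <- c(0L, zones[1] + 1L, zones[2] + 1L, zones[3] + 1L)  # zones 3+..0
  upper <- zones
  i <- 4L - zone  # zone 3 -> slot 1
  lo_i <- max(lower[i] + margin, if (zone == 3L) darkest else 0)
  hi_i <- upper[i] - margin
  if (lo_i >= hi_i)
    abort_ihc("zone too narrow for the requested margin", "ihc_config_error")
  # intensity is decreasing in concentration
  c(-log10(hi_i / 255), -log10(lo_i / 255))
}

#' Specify one synthetic tissue region
#'
#' A region is a set of image tiles sharing a target scoring zone and
#' stain concentration ranges. Per-pixel DAB and hematoxylin
#' concentrations are drawn uniformly from the ranges; by default the DAB
#' range is calibrated with [zone_concentration_range()] so every rendered
#' pixel's de-convolved DAB intensity falls inside the target zone, and
#' tissue regions carry a light-to-moderate hematoxylin counterstain
#' (concentration 0.05-0.4).
#'
#' @param target_zone `"3+"`, `"2+"`, `"1+"`, `"0"` (or integers 0-3), or
#'   `"background"` for unstained bright area (fatty tissue / empty glass,
#'   rendering above the exclusion cutoff).
#' @param area_fraction Fraction of the image occupied; fractions across a
#'   spec must sum to 1.
#' @param dab_range,hematoxylin_range Optional `c(lo, hi)` concentration
#'   overrides.
#' @param config An [ihc_config()] supplying zone boundaries.
#' @return A list of class `region_spec`.
#' @export
region_spec <- function(target_zone, area_fraction,
                        dab_range = NULL, hematoxylin_range = NULL,
                        config = ihc_config()) {
  cfg <- as_ihc_config(config)
  if (is.numeric(target_zone)) {
    stopifnot(target_zone %in% 0:3)
    target_zone <- grade_label(as.integer(target_zone))
  }
  if (!target_zone %in% c(GRADE_LABELS, "background"))
    abort_ihc("`target_zone` must be 0/1+/2+/3+ or \"background\"",
              "ihc_invalid_spec")
  if (!is.numeric(area_fraction) || area_fraction < 0 || area_fraction > 1)
    abort_ihc("`area_fraction` must lie in [0, 1]", "ihc_invalid_spec")
  if (is.null(dab_range)) {
    dab_range <- if (target_zone == "background") c(0, 0)
      else zone_concentration_range(match(target_zone, GRADE_LABELS) - 1L,
                                    cfg$zones)
  }
  if (is.null(hematoxylin_range)) {
    hematoxylin_range <- if (target_zone == "background") c(0, 0)
      else c(0.05, 0.4)
  }
  stopifnot(length(dab_range) == 2L, diff(dab_range) >= 0, dab_range[1] >= 0,
            length(hematoxylin_range) == 2L, diff(hematoxylin_range) >= 0,
            hematoxylin_range[1] >= 0)
  structure(list(target_zone = target_zone, area_fraction = area_fraction,
                 dab_range = dab_range,
                 hematoxylin_range = hematoxylin_range),
            class = "region_spec")
}

#' Default region layout for a target grade
#'
#' A realistic single-grade field of view: for positive grades, 72%
#' tumor tissue in the target zone, 13% lightly stained stroma (zone 0)
#' and 15% bright background; for grade 0, 85% zone-0 tissue and 15%
#' background. The tumor zone holds about 85% of scoreable pixels, so the
#' dominance rule assigns the target grade.
#'
#' @param grade Integer target grade 0-3.
#' @param config An [ihc_config()].
#' @return A list of `region_spec`s summing to area 1.
#' @export
grade_region_spec <- function(grade, config = ihc_config()) {
  stopifnot(grade %in% 0:3)
  if (grade == 0L) {
    list(region_spec("0", 0.85, config = config),
         region_spec("background", 0.15, config = config))
  } else {
    list(region_spec(grade_label(grade), 0.72, config = config),
         region_spec("0", 0.13, config = config),
         region_spec("background", 0.15, config = config))
  }
}

#' Render a synthetic IHC image with ground truth
#'
#' Assigns rectangular tiles to the regions of `spec` (largest-remainder
#' apportionment, tile order shuffled by `seed`), draws per-pixel DAB and
#' hematoxylin concentrations uniformly within each region's range,
#' forward-renders `RGB = background * 10^(-M c)` through the configured
#' stain matrix, quantizes to 8 bits, and adds Gaussian channel noise.
#' The ground-truth grade is computed analytically from the realized zone
#' fractions via the scoring rules (dominance, then weighted formula).
#'
#' @param spec A list of [region_spec()]s whose `area_fraction`s sum to 1,
#'   or a single `region_spec`.
#' @param size `c(height, width)` in pixels.
#' @param noise_sd Standard deviation of additive Gaussian channel noise
#'   on the 8-bit scale (default 2).
#' @param seed Integer seed; identical `(spec, size, noise_sd, seed)`
#'   reproduce the image bit-exactly.
#' @param config An [ihc_config()].
#' @param tile Tile edge length in pixels (default 8).
#' @return A list of class `synthetic_ihc`: `rgb` (`H x W x 3` integer
#'   array), `truth` (list with `grade`, `label`, `zone_fractions`,
#'   `scoreable_fraction`), `seed`, and `region_map` (`H x W` integer
#'   matrix of region indices).
#' @export
#' @examples
#' img <- render_ihc(grade_region_spec(2L), size = c(48, 48), seed = 7)
#' img$truth$label
render_ihc <- function(spec, size = c(64, 64), noise_sd = 2, seed = 1,
                       config = ihc_config(), tile = 8L) {
  cfg <- as_ihc_config(config)
  if (inherits(spec, "region_spec")) spec <- list(spec)
  if (!length(spec) || !all(vapply(spec, inherits, logical(1), "region_spec")))
    abort_ihc("`spec` must be a list of region_spec objects",
              "ihc_invalid_spec")
  fr <- vapply(spec, `[[`, numeric(1), "area_fraction")
  if (abs(sum(fr) - 1) > 1e-9)
    abort_ihc("region area fractions must sum to 1", "ihc_invalid_spec")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    abort_ihc("`noise_sd` must be non-negative", "ihc_invalid_spec")
  stopifnot(length(size) == 2L, all(size >= 1))
  H <- as.integer(size[1]); W <- as.integer(size[2])

  with_seed(seed, {
    # --- tile apportionment (largest remainder), shuffled placement
    ty <- ceiling(H / tile); tx <- ceiling(W / tile)
    n_tiles <- ty * tx
    quota <- fr * n_tiles
    n_per <- floor(quota)
    rem <- n_tiles - sum(n_per)
    if (rem > 0) {
      extra <- order(quota - n_per, decreasing = TRUE)[seq_len(rem)]
      n_per[extra] <- n_per[extra] + 1L
    }
    tile_region <- sample(rep.int(seq_along(spec), n_per))
    tmap <- matrix(tile_region, ty, tx)
    rows <- pmin((seq_len(H) - 1L) %/% tile + 1L, ty)
    cols <- pmin((seq_len(W) - 1L) %/% tile + 1L, tx)
    region_map <- tmap[rows, cols, drop = FALSE]

    # --- per-pixel concentrations
    n_px <- H * W
    cd <- numeric(n_px); chm <- numeric(n_px)
    for (i in seq_along(spec)) {
      idx <- which(region_map == i)
      if (!length(idx)) next
      r <- spec[[i]]
      cd[idx] <- stats::runif(length(idx), r$dab_range[1], r$dab_range[2])
      chm[idx] <- stats::runif(length(idx), r$hematoxylin_range[1],
                               r$hematoxylin_range[2])
    }

    # --- forward render
    M <- cfg$stain_matrix
    bg <- if (identical(cfg$background, "estimate")) c(255, 255, 255)
          else cfg$background
    od <- cbind(chm, cd, 0) %*% t(M)   # pixels x channels
    rgb <- sweep(10^(-od), 2, bg, "*")
    rgb <- round_half_up(rgb)
    if (noise_sd > 0)
      rgb <- round_half_up(rgb + stats::rnorm(length(rgb), 0, noise_sd))
    rgb <- pmin(pmax(rgb, 0), 255)
    img <- array(as.integer(rgb), dim = c(H, W, 3L))

    # --- analytic ground truth from realized region areas
    zone_of <- vapply(spec, `[[`, character(1), "target_zone")
    area <- tabulate(region_map, nbins = length(spec))
    zf <- vapply(c("3+", "2+", "1+", "0"),
                 function(z) sum(area[zone_of == z]), numeric(1))
    scoreable <- sum(zf)
    truth <- if (scoreable == 0) {
      list(grade = NA_integer_, label = NA_character_,
           zone_fractions = rep(NA_real_, 4), scoreable_fraction = 0)
    } else {
      zf <- zf / scoreable
      g <- grade_from_fractions(zf, cfg$dominance, cfg$rounding)
      list(grade = g, label = grade_label(g), zone_fractions = zf,
           scoreable_fraction = scoreable / n_px)
    }

    structure(list(rgb = img, truth = truth, seed = seed,
                   region_map = region_map),
              class = "synthetic_ihc")
  })
}

# scoring rules applied to exact zone fractions (3+, 2+, 1+, 0)
grade_from_fractions <- function(zf, dominance = 0.66, rounding = "half_up") {
  dom <- which(zf > dominance)
  if (length(dom)) return(c(3L, 2L, 1L, 0L)[dom[1]])
  ws <- sum(zf * c(3, 2, 1, 0))
  as.integer(switch(rounding, half_up = round_half_up(ws), half_even = round(ws)))
}

#' @export
print.synthetic_ihc <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("synthetic IHC image %dx%d, seed %d, ground-truth grade %s\n",
              d[1], d[2], x$seed, x$truth$label))
  invisible(x)
}

#' Generate a ground-truth-labelled synthetic cohort
#'
#' Renders one synthetic image per sample according to a subtype-by-grade
#' count table and returns the images together with a cohort record table
#' carrying receptor status, menopause and chemotherapy labels, the
#' ground-truth (`manual_grade`) and, optionally, the pipeline-scored
#' (`auto_grade`) grade for each sample.
#'
#' @param counts Data frame with columns `subtype` (e.g. `"ER+PgR+HER2-"`),
#'   `grade` (0-3 or `"0"`/`"1+"`/`"2+"`/`"3+"`), and `n` (non-negative
#'   counts).
#' @param seed Integer master seed; sample `i` uses `seed + i`.
#' @param size,noise_sd,config Passed to [render_ihc()].
#' @param score Compute `auto_grade` by running [score_image()] on each
#'   rendered image (default `TRUE`).
#' @param p_premenopause,p_postchemo Probabilities used to draw the
#'   menopause (pre = age at most 50) and preoperative-chemotherapy labels;
#'   defaults reflect a typical grade-III breast-carcinoma cohort (48/108
#'   premenopausal, 16/108 post-chemotherapy).
#' @return A list with `records` (data frame: `sample_id`, `subtype`,
#'   `er`, `pgr`, `her2`, `menopause`, `chemo`, `manual_grade`,
#'   `auto_grade`) and `images` (list of `synthetic_ihc`).
#' @export
generate_cohort <- function(counts, seed = 1, size = c(64, 64), noise_sd = 2,
                            config = ihc_config(), score = TRUE,
                            p_premenopause = 48 / 108,
                            p_postchemo = 16 / 108) {
  cfg <- as_ihc_config(config)
  if (!is.data.frame(counts) ||
      !all(c("subtype", "grade", "n") %in% names(counts)))
    abort_ihc("`counts` needs columns subtype, grade, n", "ihc_invalid_spec")
  if (any(counts$n < 0) || any(counts$n != floor(counts$n)))
    abort_ihc("counts must be non-negative integers", "ihc_invalid_spec")
  grades <- normalize_grade(counts$grade)

  rows <- list(); images <- list(); k <- 0L
  for (i in seq_len(nrow(counts))) {
    st <- parse_subtype(counts$subtype[i])
    for (j in seq_len(counts$n[i])) {
      k <- k + 1L
      img <- render_ihc(grade_region_spec(grades[i], cfg), size = size,
                        noise_sd = noise_sd, seed = seed + k, config = cfg)
      auto <- if (score) score_image(img$rgb, cfg)$grade$label
              else NA_character_
      # demographic draws use an offset seed, separate from the image stream
      labels <- with_seed(seed + k + 1000003L, stats::runif(2))
      rows[[k]] <- data.frame(
        sample_id = sprintf("S%03d", k),
        subtype = counts$subtype[i],
        er = st["er"], pgr = st["pgr"], her2 = st["her2"],
        menopause = if (labels[1] < p_premenopause) "pre" else "post",
        chemo = if (labels[2] < p_postchemo) "post" else "pre",
        manual_grade = grade_label(grades[i]),
        auto_grade = auto,
        stringsAsFactors = FALSE
      )
      images[[k]] <- img
    }
  }
  records <- if (k == 0L) empty_records() else do.call(rbind, rows)
  rownames(records) <- NULL
  list(records = records, images = images)
}

empty_records <- function() {
  data.frame(sample_id = character(), subtype = character(),
             er = character(), pgr = character(), her2 = character(),
             menopause = character(), chemo = character(),
             manual_grade = character(), auto_grade = character(),
             stringsAsFactors = FALSE)
}

parse_subtype <- function(subtype) {
  s <- gsub("[[:space:]]", "", subtype)
  status <- function(marker) {
    m <- regmatches(s, regexpr(paste0(marker, "[+-]"), s, ignore.case = TRUE))
    if (!length(m))
      abort_ihc(sprintf("cannot parse %s status from subtype \"%s\"",
                        marker, subtype), "ihc_invalid_spec")
    if (endsWith(m, "+")) "positive" else "negative"
  }
  c(er = status("ER"), pgr = status("PgR"), her2 = status("HER2"))
}

normalize_grade <- function(grade) {
  if (is.numeric(grade)) {
    if (!all(grade %in% 0:3))
      abort_ihc("grades must be in 0..3", "ihc_invalid_spec")
    return(as.integer(grade))
  }
  idx <- match(as.character(grade), GRADE_LABELS)
  if (anyNA(idx))
    abort_ihc("grades must be 0, 1+, 2+ or 3+", "ihc_invalid_spec")
  idx - 1L
}
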