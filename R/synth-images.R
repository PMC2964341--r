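#' Rendering parameters for synthetic two-channel fields
#'
#' Intensities are on the 16-bit camera scale. The pixel model is Poisson
#' shot noise on the expected signal plus additive Gaussian read noise.
#'
#' @param nucleus_dna expected DNA-channel counts inside a nucleus
#' @param background expected counts outside any cell (both channels)
#' @param reporter_hi expected reporter counts in the compartment where a
#'   class concentrates signal
#' @param reporter_lo expected reporter counts in the complementary
#'   compartment of a reporter-positive cell
#' @param nucleolar_base expected nucleoplasmic reporter counts of a
#'   nucleolar-phenotype cell
#' @param nucleolar_contrast multiplicative enrichment of reporter in
#'   nucleolar subregions over `nucleolar_base`
#' @param read_noise_sd Gaussian read-noise standard deviation (counts)
#' @param cyto_width cytoplasm ring width in pixels around each nucleus
#' @param touch_prob probability that a new nucleus is deliberately placed
#'   touching an existing one (exercises watershed splitting)
#' @param max_attempts placement attempts per cell before giving up
#' @return named list of rendering parameters
#' @export
render_params <- function(nucleus_dna = 3000, background = 200,
                          reporter_hi = 2000, reporter_lo = 400,
                          nucleolar_base = 800, nucleolar_contrast = 3,
                          read_noise_sd = 30, cyto_width = 5,
                          touch_prob = 0, max_attempts = 200) {
  list(nucleus_dna = nucleus_dna, background = background,
       reporter_hi = reporter_hi, reporter_lo = reporter_lo,
       nucleolar_base = nucleolar_base,
       nucleolar_contrast = nucleolar_contrast,
       read_noise_sd = read_noise_sd, cyto_width = cyto_width,
       touch_prob = touch_prob, max_attempts = max_attempts)
}

# map any readout's class labels onto the four rendering archetypes
render_archetype <- function(class_label) {
  switch(class_label,
    cytoplasmic = , cytoplasm = "cytoplasmic",
    nucleoplasmic = , nucleoplasm = , nucleus = "nucleoplasmic",
    nucleolar = , nucleolus = "nucleolar",
    no_reporter = "no_reporter",
    mitotic = "mitotic",
    debris = "debris",
    stop("no rendering archetype for class '", class_label, "'")
  )
}

#' Render one synthetic two-channel well image
#'
#' Draws `n_cells` true classes from the phenotype mix, places elliptical
#' nuclei without overlap (optionally touching, to exercise watershed
#' splitting), and renders a DNA channel and a reporter channel on a 16-bit
#' scale. Reporter placement follows the class: nucleolar cells concentrate
#' signal in small intranuclear nucleolar subregions placed in the inner
#' half of the nucleus; nucleoplasmic cells fill the nucleus uniformly;
#' cytoplasmic cells show a perinuclear ring; reporter-negative cells show
#' background only; mitotic cells are small bright condensed DNA objects;
#' debris is a dim irregular fragment.
#'
#' @param well_spec list with `mix` (phenotype mix, must sum to 1) and
#'   `n_cells` (count, may be 0)
#' @param image_size field edge length in pixels (>= 128)
#' @param seed integer seed; identical (well_spec, seed) give bit-identical
#'   images
#' @param readout readout id naming the class taxonomy of `mix`
#' @param params rendering parameters from [render_params()]
#' @return list: `dna` and `reporter` (image_size x image_size numeric
#'   matrices of 16-bit counts) and `truth` (list: `cells` data.frame
#'   (cell_id, true_class, x, y), `nucleus_mask` and `nucleolus_mask`
#'   integer label matrices keyed by cell_id)
#' @export
generate_cell_image <- function(well_spec, image_size = 256, seed = 1L,
                                readout = "rps2", params = render_params()) {
  if (image_size < 128) stop("image_size must be at least 128 pixels")
  n <- well_spec$n_cells
  stopifnot(n >= 0)
  mix <- check_mix(well_spec$mix, readout)
  set.seed(seed)

  S <- image_size
  dna <- matrix(params$background, S, S)
  rep_ch <- matrix(params$background, S, S)
  nuc_lab <- matrix(0L, S, S)
  nol_lab <- matrix(0L, S, S)
  cells <- data.frame(cell_id = integer(), true_class = character(),
                      x = numeric(), y = numeric(),
                      stringsAsFactors = FALSE)
  if (n > 0) {
    classes <- sample(names(mix), n, replace = TRUE, prob = mix)
    placed <- data.frame(x = numeric(), y = numeric(), r = numeric())
    margin <- 16
    cid <- 0L
    for (ci in seq_len(n)) {
      arch <- render_archetype(classes[ci])
      a <- switch(arch, mitotic = stats::runif(1, 5, 7),
                  debris = stats::runif(1, 3, 5), stats::runif(1, 9, 13))
      b <- switch(arch, mitotic = stats::runif(1, 4, 6),
                  debris = stats::runif(1, 2, 4), stats::runif(1, 7, 10))
      theta <- stats::runif(1, 0, pi)
      reff <- max(a, b)
      ok <- FALSE
      want_touch <- nrow(placed) > 0 && stats::runif(1) < params$touch_prob
      for (att in seq_len(params$max_attempts)) {
        if (want_touch) {
          j <- sample.int(nrow(placed), 1)
          ang <- stats::runif(1, 0, 2 * pi)
          d0 <- 0.95 * (placed$r[j] + reff)
          cx <- placed$x[j] + d0 * cos(ang)
          cy <- placed$y[j] + d0 * sin(ang)
          others <- setdiff(seq_len(nrow(placed)), j)
          sep_ok <- cx > margin && cx < S - margin && cy > margin &&
            cy < S - margin &&
            (!length(others) ||
             all(sqrt((placed$x[others] - cx)^2 +
                      (placed$y[others] - cy)^2) >
                 placed$r[others] + reff + 2))
        } else {
          cx <- stats::runif(1, margin, S - margin)
          cy <- stats::runif(1, margin, S - margin)
          sep_ok <- !nrow(placed) ||
            all(sqrt((placed$x - cx)^2 + (placed$y - cy)^2) >
                placed$r + reff + params$cyto_width + 2)
        }
        if (sep_ok) { ok <- TRUE; break }
      }
      if (!ok) next
      cid <- cid + 1L
      placed <- rbind(placed, data.frame(x = cx, y = cy, r = reff))
      cells <- rbind(cells, data.frame(cell_id = cid, true_class = classes[ci],
                                       x = cx, y = cy,
                                       stringsAsFactors = FALSE))
      # normalized elliptical radius over the bounding box
      x0 <- max(1, floor(cx - reff - 1)); x1 <- min(S, ceiling(cx + reff + 1))
      y0 <- max(1, floor(cy - reff - 1)); y1 <- min(S, ceiling(cy + reff + 1))
      xs <- x0:x1; ys <- y0:y1
      dx <- outer(xs - cx, rep(1, length(ys)))
      dy <- outer(rep(1, length(xs)), ys - cy)
      u <- (dx * cos(theta) + dy * sin(theta)) / a
      v <- (-dx * sin(theta) + dy * cos(theta)) / b
      rn <- sqrt(u^2 + v^2)
      inside <- rn <= 1 & nuc_lab[xs, ys] == 0L
      sub <- nuc_lab[xs, ys]; sub[inside] <- cid; nuc_lab[xs, ys] <- sub

      dna_val <- switch(arch, mitotic = 2 * params$nucleus_dna,
                        debris = 0.4 * params$nucleus_dna,
                        params$nucleus_dna)
      dsub <- dna[xs, ys]; dsub[inside] <- dna_val; dna[xs, ys] <- dsub

      # nucleolar subregions: 1-3 small discs in the inner half of the nucleus
      nol_here <- matrix(FALSE, length(xs), length(ys))
      if (arch %in% c("nucleolar", "nucleoplasmic", "cytoplasmic")) {
        for (k in seq_len(sample(1:3, 1))) {
          rr <- stats::runif(1, 0, 0.45)
          ang <- stats::runif(1, 0, 2 * pi)
          ncx <- cx + rr * a * cos(ang) * cos(theta) -
                 rr * b * sin(ang) * sin(theta)
          ncy <- cy + rr * a * cos(ang) * sin(theta) +
                 rr * b * sin(ang) * cos(theta)
          nrad <- stats::runif(1, 2, 3.5)
          disc <- (outer(xs - ncx, rep(1, length(ys)))^2 +
                   outer(rep(1, length(xs)), ys - ncy)^2) <= nrad^2
          nol_here <- nol_here | (disc & inside)
        }
        nsub <- nol_lab[xs, ys]; nsub[nol_here] <- cid; nol_lab[xs, ys] <- nsub
        # nucleoli exclude DNA: darker in the DNA channel
        dsub <- dna[xs, ys]; dsub[nol_here] <- 0.6 * dna_val
        dna[xs, ys] <- dsub
      }

      ring <- rn > 1 & rn <= 1 + params$cyto_width / ((a + b) / 2) &
        nuc_lab[xs, ys] == 0L
      rvals <- rep_ch[xs, ys]
      if (arch == "cytoplasmic") {
        rvals[inside] <- params$reporter_lo
        rvals[ring] <- params$reporter_hi
      } else if (arch == "nucleoplasmic") {
        rvals[inside] <- params$reporter_hi
        rvals[ring] <- params$reporter_lo
      } else if (arch == "nucleolar") {
        rvals[inside] <- params$nucleolar_base
        rvals[nol_here] <- params$nucleolar_base * params$nucleolar_contrast
        rvals[ring] <- params$reporter_lo
      } else if (arch == "mitotic") {
        rvals[inside | ring] <- params$reporter_lo
      } # no_reporter, debris: background stays
      rep_ch[xs, ys] <- rvals
    }
  }
  # Poisson shot noise + Gaussian read noise, clipped to the 16-bit range
  noisy <- function(m) {
    v <- stats::rpois(length(m), lambda = as.vector(m)) +
      stats::rnorm(length(m), 0, params$read_noise_sd)
    matrix(pmin(pmax(round(v), 0), 65535), nrow(m), ncol(m))
  }
  list(dna = noisy(dna), reporter = noisy(rep_ch),
       truth = list(cells = cells, nucleus_mask = nuc_lab,
                    nucleolus_mask = nol_lab))
}
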