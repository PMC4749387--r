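#' Simulate an ontogenetic study of sutural fusion
#'
#' Generates a specimen series with known ages, a size-age growth map, and
#' a character matrix whose closure trajectories follow one of the two
#' empirical regimes: `"closing"` (sutures progressively narrow and
#' obliterate, the avian pattern) or `"widening"` (sutures open up with
#' maturity, except designated midline characters that obliterate during
#' embryonic development, the crocodylian pattern).
#'
#' Specimen `i` has age `a_i` uniform over `age_range` and a skull length
#' from a saturating (von Bertalanffy style) growth curve plus Gaussian
#' noise. Character `k` has a latent maturity
#' `u = clamp((a_i - onset_k)/duration_k, 0, 1)`; closing mode scores the
#' closure state `round(3u)`, widening mode `2 - round(2u)`: a widening
#' suture starts closed (2) and descends only to 0 (open); it never reaches
#' 3, since complete obliteration is reserved for the designated embryonic
#' midline characters, and "wider than open" is expressible only in the
#' histological simulator. Interdigitation characters score `round(2u)` in
#' both modes. With probability `p` a cell becomes the polymorphic set
#' `{s, s +/- 1}` clipped to the valid range.
#'
#' @param n_specimens number of specimens (default 24, the emu series size).
#' @param sutures_per_group named counts of simulated sutures per anatomical
#'   group; each suture yields one closure and one interdigitation
#'   character.
#' @param mode `"closing"` or `"widening"`.
#' @param n_multiview number of sutures whose degree of closure is scored in
#'   a second anatomical view, each adding one duplicate closure character
#'   (the fusion of a suture can be assessed wherever its contact points are
#'   visible, and such matrices carry more closure than interdigitation
#'   characters). Defaults to 2 in closing mode and 6 in widening mode,
#'   mirroring the character arithmetic of the emulated study series
#'   (20 sutures -> 42 characters; the widening series carried 6 extra view
#'   characters).
#' @param n_embryonic_obliterations widening mode only: midline closure
#'   characters fixed at `{3}` in every specimen.
#' @param poly_prob probability a cell is recorded polymorphic.
#' @param age_range years, uniform sampling range.
#' @param onset_frac onsets are drawn uniform over
#'   `age_range[1] + c(0, onset_frac) * diff(age_range)`. The default 0.6,
#'   together with the default durations, lets almost every transition run
#'   to completion within the sampled lifespan -- the emulated series end
#'   near their trajectory endpoints (the most mature specimens are close
#'   to fully obliterated in the closing regime and close to fully open in
#'   the widening regime).
#' @param duration_range years, uniform per-character transition durations.
#' @param growth list: `l0` (hatchling skull length mm), `linf` (asymptotic
#'   length), `k` (growth rate per year), `sd` (measurement noise, mm).
#' @param seed integer seed; identical configurations and seeds give
#'   byte-identical studies.
#' @return object of class `simulated_study`: `matrix`
#'   (a [character_matrix()]), `records` (specimen metadata with true
#'   `age_years` and maturity-quartile categories), and `truth` (onsets,
#'   durations, onset order, embryonic characters, parameters).
#' @export
sim_ontogeny_study <- function(n_specimens = 24,
                               sutures_per_group = c(facial = 5, cranial = 8,
                                                     palatal = 4, braincase = 3),
                               mode = c("closing", "widening"),
                               n_multiview = NULL,
                               n_embryonic_obliterations = 2,
                               poly_prob = 0.1,
                               age_range = c(0, 20),
                               onset_frac = 0.6,
                               duration_range = c(2, 6),
                               growth = list(l0 = 55, linf = 160, k = 0.15,
                                             sd = 3),
                               seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(poly_prob >= 0, poly_prob <= 1, all(duration_range > 0),
            n_specimens >= 2)
  if (is.null(n_multiview)) n_multiview <- if (mode == "closing") 2L else 6L
  groups <- rep(names(sutures_per_group), sutures_per_group)
  n_sut <- length(groups)
  if (mode == "widening" && n_embryonic_obliterations > n_sut)
    stop("more embryonic obliterations than closure characters")
  set.seed(as.integer(seed))
  sut_names <- sprintf("%s_suture_%02d", groups, stats::ave(seq_len(n_sut),
                        groups, FUN = seq_along))
  onsets <- stats::runif(n_sut, age_range[1],
                         age_range[1] + onset_frac * diff(age_range))
  durations <- stats::runif(n_sut, duration_range[1], duration_range[2])
  embry <- integer(0)
  if (mode == "widening" && n_embryonic_obliterations > 0)
    embry <- sort(sample.int(n_sut, n_embryonic_obliterations))
  mv <- setdiff(seq_len(n_sut), embry)
  mv <- mv[seq_len(min(n_multiview, length(mv)))]
  ages <- sort(stats::runif(n_specimens, age_range[1], age_range[2]))
  skull <- growth$l0 + (growth$linf - growth$l0) * (1 - exp(-growth$k * ages)) +
    stats::rnorm(n_specimens, 0, growth$sd)
  skull <- pmax(skull, 1)
  ids <- sprintf("SIM%03d", seq_len(n_specimens))

  chars <- rbind(
    data.frame(char_id = sprintf("clo%02d", seq_len(n_sut)),
               suture = sut_names, group = groups, aspect = "closure",
               view = "dorsal", max_state = 3L, stringsAsFactors = FALSE),
    if (length(mv))
      data.frame(char_id = sprintf("clv%02d", seq_along(mv)),
                 suture = sut_names[mv], group = groups[mv],
                 aspect = "closure", view = "palatal", max_state = 3L,
                 stringsAsFactors = FALSE),
    data.frame(char_id = sprintf("int%02d", seq_len(n_sut)),
               suture = sut_names, group = groups, aspect = "interdigitation",
               view = "none", max_state = 2L, stringsAsFactors = FALSE))
  # suture index driving each character's latent trajectory
  sut_of <- c(seq_len(n_sut), mv, seq_len(n_sut))
  embry_char <- which(sut_of %in% embry & chars$aspect == "closure")

  cells <- base::matrix(vector("list", n_specimens * nrow(chars)),
                        nrow = n_specimens)
  for (i in seq_len(n_specimens)) {
    u_sut <- pmin(pmax((ages[i] - onsets) / durations, 0), 1)
    u <- u_sut[sut_of]
    states <- integer(nrow(chars))
    is_clo <- chars$aspect == "closure"
    states[is_clo] <- if (mode == "closing") as.integer(round(3 * u[is_clo]))
                      else 2L - as.integer(round(2 * u[is_clo]))  # never {3}
    states[embry_char] <- 3L
    states[!is_clo] <- as.integer(round(2 * u[!is_clo]))
    maxs <- chars$max_state
    for (j in seq_along(states)) {
      s <- states[j]
      poly_ok <- poly_prob > 0 && !(j %in% embry_char) &&
        stats::runif(1) < poly_prob
      cells[[i, j]] <- if (poly_ok) {
        s2 <- s + sample(c(-1L, 1L), 1L)
        if (s2 < 0L || s2 > maxs[j]) s2 <- s - (s2 - s)
        sort(unique(c(s, s2)))
      } else s
    }
  }
  matrix <- character_matrix(ids, cells, chars)
  category <- cut(ages,
                  breaks = stats::quantile(ages, probs = seq(0, 1, 0.25)),
                  labels = CATEGORY_LEVELS, include.lowest = TRUE)
  records <- data.frame(specimen_id = ids,
                        skull_length_mm = skull,
                        total_length_cm = skull / 1.5,
                        age_years = ages,
                        sex = "unknown", status = "unknown",
                        category = as.character(category),
                        stringsAsFactors = FALSE)
  structure(list(matrix = matrix, records = records,
                 truth = list(mode = mode, onsets = onsets,
                              durations = durations,
                              onset_order = order(onsets),
                              embryonic = embry,
                              multiview = mv,
                              sutures = sut_names,
                              growth = growth, seed = as.integer(seed))),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("simulated_study (", x$truth$mode, " mode): ", sep = "")
  cat(length(x$matrix$taxa), "specimens,", nrow(x$matrix$chars), "characters\n")
  invisible(x)
}

#' Add coder noise to a character matrix
#'
#' Each cell is independently replaced, with probability `q`, by an
#' adjacent-state singleton: a state drawn from the cell shifted by one
#' (clipped to the valid range, taking the other direction at a boundary).
#' Missing cells are left untouched.
#'
#' @param matrix a [character_matrix()].
#' @param q per-cell error probability.
#' @param seed integer seed.
#' @return a recoded `character_matrix`.
#' @export
sim_coder_noise <- function(matrix, q, seed = 1L) {
  stopifnot(q >= 0, q <= 1)
  set.seed(as.integer(seed))
  cells <- matrix$cells
  maxs <- matrix$chars$max_state
  for (j in seq_len(ncol(cells))) {
    for (i in seq_len(nrow(cells))) {
      cell <- cells[[i, j]]
      if (is_missing_cell(cell)) next
      if (stats::runif(1) >= q) next
      s <- if (length(cell) == 1L) cell else sample(cell, 1L)
      s2 <- s + sample(c(-1L, 1L), 1L)
      if (s2 < 0L || s2 > maxs[j]) s2 <- s - (s2 - s)
      if (s2 < 0L || s2 > maxs[j]) next   # no adjacent state exists
      cells[[i, j]] <- s2
    }
  }
  character_matrix(matrix$taxa, cells, matrix$chars)
}

#' Simulate a sinusoidal suture section
#'
#' Builds the geometry the histomorphometric width estimator is validated
#' on: a central trace following a sinusoid of given amplitude and
#' wavelength (interdigitation), surrounded by a band of constant
#' perpendicular width. The polygon's shoelace area divided by the trace
#' length recovers the nominal width (exactly for a straight band, within a
#' small discretization error for a curved one).
#'
#' @param width nominal band width (um).
#' @param amplitude sinusoid amplitude (um); 0 gives a rectangle.
#' @param wavelength sinusoid wavelength (um).
#' @param trace_length arc length of the central trace (um).
#' @param n_points samples along the trace.
#' @param phase phase offset (radians).
#' @return object of class `section_polygon` with `loop` (closed outline)
#'   and `trace` (central polyline); an error if the band would
#'   self-intersect (half-width exceeding the minimum radius of curvature).
#' @export
sim_suture_section <- function(width, amplitude = 0, wavelength = 400,
                               trace_length = 1000, n_points = 600,
                               phase = 0) {
  stopifnot(width > 0, wavelength > 0, trace_length > 0, amplitude >= 0)
  omega <- 2 * pi / wavelength
  # find the x extent whose arc length equals trace_length
  arc <- function(X) {
    xs <- seq(0, X, length.out = 4096)
    sum(sqrt(1 + (amplitude * omega * cos(omega * xs + phase))^2) * c(0, diff(xs)))
  }
  X <- stats::uniroot(function(X) arc(X) - trace_length,
                      c(trace_length * 1e-6, trace_length * 1.01))$root
  x <- seq(0, X, length.out = n_points)
  y <- amplitude * sin(omega * x + phase)
  dy <- amplitude * omega * cos(omega * x + phase)
  norm <- sqrt(1 + dy^2)
  nx <- -dy / norm; ny <- 1 / norm
  upper <- cbind(x + nx * width / 2, y + ny * width / 2)
  lower <- cbind(x - nx * width / 2, y - ny * width / 2)
  # where the offset half-width exceeds the local radius of curvature (at
  # tight interdigitation crests) the raw offset folds into small loops;
  # trim them -- the bone fronts converge there, so the unossified space is
  # genuinely reduced
  upper <- trim_polyline_loops(upper)
  lower <- trim_polyline_loops(lower)
  loop <- rbind(upper, lower[rev(seq_len(nrow(lower))), ])
  if (polylines_intersect(upper, lower) || !is_simple_polygon(loop))
    stop("band self-intersects: width ", width, " is too large for ",
         "amplitude ", amplitude, " at wavelength ", wavelength)
  structure(list(loop = loop, trace = cbind(x, y),
                 width = width, amplitude = amplitude,
                 wavelength = wavelength),
            class = "section_polygon")
}

# intersection point of segments p1-p2 and p3-p4, or NULL
segment_intersection <- function(p1, p2, p3, p4) {
  d1 <- p2 - p1; d2 <- p4 - p3
  denom <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(denom) < 1e-12) return(NULL)
  t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / denom
  u <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / denom
  if (t < 0 || t > 1 || u < 0 || u > 1) return(NULL)
  p1 + t * d1
}

# indices (i, j) of the first pair of non-adjacent crossing segments
first_polyline_crossing <- function(P, Q = NULL) {
  same <- is.null(Q)
  if (same) Q <- P
  np <- nrow(P) - 1L; nq <- nrow(Q) - 1L
  ax <- P[1:np, 1]; ay <- P[1:np, 2]
  bx <- P[2:(np + 1), 1]; by <- P[2:(np + 1), 2]
  cx <- Q[1:nq, 1]; cy <- Q[1:nq, 2]
  dx <- Q[2:(nq + 1), 1]; dy <- Q[2:(nq + 1), 2]
  ii <- rep(seq_len(np), each = nq); jj <- rep(seq_len(nq), np)
  keep <- if (same) jj > ii + 1L else rep(TRUE, length(ii))
  ii <- ii[keep]; jj <- jj[keep]
  cr <- function(ox, oy, px, py, qx, qy)
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  d1 <- cr(ax[ii], ay[ii], bx[ii], by[ii], cx[jj], cy[jj])
  d2 <- cr(ax[ii], ay[ii], bx[ii], by[ii], dx[jj], dy[jj])
  d3 <- cr(cx[jj], cy[jj], dx[jj], dy[jj], ax[ii], ay[ii])
  d4 <- cr(cx[jj], cy[jj], dx[jj], dy[jj], bx[ii], by[ii])
  hit <- which(d1 * d2 < 0 & d3 * d4 < 0)
  if (!length(hit)) return(NULL)
  k <- hit[1]
  c(i = ii[k], j = jj[k])
}

# remove self-intersection loops from an open polyline (untrimmed offset
# curve -> trimmed offset curve)
trim_polyline_loops <- function(P, max_iter = 100L) {
  for (it in seq_len(max_iter)) {
    x <- first_polyline_crossing(P)
    if (is.null(x)) return(P)
    q <- segment_intersection(P[x["i"], ], P[x["i"] + 1L, ],
                              P[x["j"], ], P[x["j"] + 1L, ])
    P <- rbind(P[seq_len(x["i"]), , drop = FALSE], q,
               P[seq(x["j"] + 1L, nrow(P)), , drop = FALSE])
  }
  stop("offset trimming did not converge")
}

polylines_intersect <- function(P, Q) !is.null(first_polyline_crossing(P, Q))
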