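## Seeded head phantoms: closed superellipsoid-based surfaces with angular
## deformation fields emulating the cross-sectional shape regimes of the
## common single-suture craniosynostosis phenotypes, plus parametric
## landmark placement. They make the whole pipeline testable without CT.
##
## The cross-section radius at azimuth phi (degrees from anterior, positive
## toward the patient's left) is a superellipse whose anterior sector can be
## angularly widened (flat broad forehead, brachycephaly) or sharpened
## (pointed keel forehead, trigonocephaly), modulated by Gaussian angular
## bosses at the forehead and occiput, a one-sided frontal flattening with a
## deviated frontal apex for plagiocephaly, and an optional random low-order
## harmonic wobble emulating normal inter-subject shape variation.
## Vertically the section is scaled by an ellipsoidal profile, giving a
## closed watertight surface.

.phantom_defaults <- list(
  control = list(
    a = 70.4, b = 55.0, n_post = 2.0, n_front = 2.0,
    front_widen = 0.47, widen_width = 40, back_widen = 0.28, back_width = 45,
    boss_f_amp = 0.030, boss_f_width = 22, boss_f_pow = 2, apex_dev = 0,
    boss_o_amp = 0.020, boss_o_width = 45,
    flat_amp = 0, flat_center = 0, flat_width = 35,
    wobble_amp = 0.007),
  scaphocephaly = list(
    a = 74.0, b = 51.0, n_post = 2.0, n_front = 2.0,
    front_widen = 0.78, widen_width = 48, back_widen = 0, back_width = 45,
    boss_f_amp = 0.035, boss_f_width = 20, boss_f_pow = 2, apex_dev = 0,
    boss_o_amp = 0.085, boss_o_width = 55,
    flat_amp = 0, flat_center = 0, flat_width = 35,
    wobble_amp = 0.004),
  trigonocephaly = list(
    a = 67.6, b = 55.0, n_post = 2.0, n_front = 2.0,
    front_widen = -0.25, widen_width = 40, back_widen = 0.30, back_width = 45,
    boss_f_amp = 0.075, boss_f_width = 24, boss_f_pow = 2, apex_dev = 0,
    boss_o_amp = 0, boss_o_width = 50,
    flat_amp = 0, flat_center = 0, flat_width = 35,
    wobble_amp = 0.004),
  brachycephaly = list(
    a = 66.0, b = 56.0, n_post = 2.0, n_front = 2.0,
    front_widen = 0.78, widen_width = 52, back_widen = 0.45, back_width = 48,
    boss_f_amp = 0.035, boss_f_width = 20, boss_f_pow = 2, apex_dev = 0,
    boss_o_amp = 0.020, boss_o_width = 45,
    flat_amp = 0, flat_center = 0, flat_width = 35,
    wobble_amp = 0.004),
  plagio_anterior_right = list(
    a = 66.5, b = 55.0, n_post = 2.0, n_front = 2.0,
    front_widen = 0.18, widen_width = 40, back_widen = 0.15, back_width = 45,
    boss_f_amp = 0.115, boss_f_width = 20, boss_f_pow = 2, apex_dev = -34,
    boss_o_amp = 0.030, boss_o_width = 45,
    flat_amp = 0.065, flat_center = -58, flat_width = 35,
    wobble_amp = 0.004),
  plagio_anterior_left = list(
    a = 66.5, b = 55.0, n_post = 2.0, n_front = 2.0,
    front_widen = 0.18, widen_width = 40, back_widen = 0.15, back_width = 45,
    boss_f_amp = 0.115, boss_f_width = 20, boss_f_pow = 2, apex_dev = 34,
    boss_o_amp = 0.030, boss_o_width = 45,
    flat_amp = 0.065, flat_center = 58, flat_width = 35,
    wobble_amp = 0.004)
)

#' Phenotypes known to the phantom generator
#' @return character vector of the six labels.
#' @export
phantom_phenotypes <- function() names(.phantom_defaults)

#' Phantom specification
#'
#' Builds the parameter set for one synthetic head, starting from the
#' per-phenotype defaults and applying any overrides. Key parameters:
#' `a`/`b` anterior-posterior and lateral cross-section semi-axes (mm);
#' `n_front`/`n_post` superellipse exponents blended across the anterior
#' half (below 2 = pointed forehead, above 2 = flat broad forehead);
#' Gaussian angular bosses at the forehead (`boss_f_*`, center offset
#' `apex_dev` in degrees, negative = toward the patient's right) and occiput
#' (`boss_o_*`); a one-sided frontal flattening (`flat_*`) for
#' plagiocephaly; `wobble_amp`, the per-harmonic SD of a random low-order
#' harmonic field (orders 2-3) emulating normal shape variation (0 disables it);
#' `noise_sd`, vertex-wise Gaussian radial noise in mm
#' (spatially smoothed over the surface, as extraction error would be).
#'
#' @param phenotype one of [phantom_phenotypes()].
#' @param noise_sd vertex noise SD in mm (default 0).
#' @param seed integer seed driving wobble and noise.
#' @param n_theta,n_psi mesh resolution (azimuthal and polar divisions).
#' @param wobble_amp override the phenotype's wobble amplitude; the
#'   noise-free regimes are defined at `wobble_amp = 0`.
#' @param ... overrides for any default listed above.
#' @return list of class `cranio_phantom_spec`.
#' @export
phantom_spec <- function(phenotype, noise_sd = 0, seed = 1L,
                         n_theta = 192L, n_psi = 64L, wobble_amp = 0, ...) {
  if (!phenotype %in% names(.phantom_defaults))
    cranio_abort("cranio_spec_error",
                 paste("unknown phenotype:", phenotype))
  spec <- .phantom_defaults[[phenotype]]
  spec$wobble_amp <- wobble_amp
  dots <- list(...)
  bad <- setdiff(names(dots), c(names(spec), "z_center", "c_vert",
                                "ex_phi", "po_phi"))
  if (length(bad))
    cranio_abort("cranio_spec_error",
                 paste("unknown phantom parameters:", paste(bad, collapse = ",")))
  spec[names(dots)] <- dots
  spec$phenotype <- phenotype
  spec$noise_sd <- noise_sd
  spec$seed <- as.integer(seed)
  spec$n_theta <- as.integer(n_theta)
  spec$n_psi <- as.integer(n_psi)
  if (is.null(spec$z_center)) spec$z_center <- 30
  if (is.null(spec$c_vert)) spec$c_vert <- 75
  if (is.null(spec$ex_phi)) spec$ex_phi <- 38
  if (is.null(spec$po_phi)) spec$po_phi <- 105
  if (spec$a <= 0 || spec$b <= 0 || spec$noise_sd < 0 ||
      spec$n_theta < 16 || spec$n_psi < 8)
    cranio_abort("cranio_spec_error", "invalid phantom parameters")
  class(spec) <- "cranio_phantom_spec"
  spec
}

## wrap angle difference to [-180, 180)
.wrap180 <- function(x) ((x + 180) %% 360) - 180

## cross-section radius (mm) at azimuth phi (deg from anterior, + = left)
.phantom_radius2d <- function(phi_deg, spec, wobble = NULL) {
  phi_w <- .wrap180(phi_deg)
  ## angular warps: widen (> 0) or sharpen (< 0) the frontal peak and the
  ## occipital peak while keeping both apices fixed at 0 / 180
  delta <- phi_w - sign(phi_w) * 180        # signed offset from the occiput
  phi_eff <- phi_w -
    spec$front_widen * phi_w * exp(-0.5 * (phi_w / spec$widen_width)^2) -
    spec$back_widen * delta * exp(-0.5 * (delta / spec$back_width)^2)
  phi <- phi_eff * pi / 180
  w_ant <- ((1 + cos(phi)) / 2)^2           # 1 at forehead, 0 at occiput
  n <- spec$n_post + (spec$n_front - spec$n_post) * w_ant
  r_se <- (abs(cos(phi) / spec$a)^n + abs(sin(phi) / spec$b)^n)^(-1 / n)
  phi <- phi_w * pi / 180                   # bosses act at true azimuth
  g <- function(center, width, pow = 2)
    exp(-0.5 * abs(.wrap180(phi_deg - center) / width)^pow)
  mod <- 1 +
    spec$boss_f_amp * g(spec$apex_dev, spec$boss_f_width, spec$boss_f_pow) +
    spec$boss_o_amp * g(180, spec$boss_o_width) -
    spec$flat_amp * g(spec$flat_center, spec$flat_width)
  if (!is.null(wobble)) {
    for (i in seq_along(wobble$order))
      mod <- mod + wobble$cosc[i] * cos(wobble$order[i] * phi) +
                   wobble$sinc[i] * sin(wobble$order[i] * phi)
  }
  r_se * mod
}

#' Generate one head phantom
#'
#' Builds the closed triangle mesh and the four external landmarks for a
#' phantom spec. Landmarks sit exactly on the noise-free surface in the
#' z = 0 plane: exocanthions anterior-lateral at azimuth +/- `ex_phi`,
#' porions posterior-lateral at +/- `po_phi`, so the landmark-defined base
#' plane is z = 0 and the analysis plane z = 40 mm. Wobble and vertex noise
#' are drawn from the spec's seed, so generation is reproducible.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `cranio_phantom`: `mesh` (a `cranio_mesh`),
#'   `landmarks` (a `cranio_landmarks`), `label`, `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "cranio_phantom_spec"))
    cranio_abort("cranio_spec_error", "spec must come from phantom_spec()")
  rng <- .with_seed(spec$seed)
  wobble <- NULL
  if (spec$wobble_amp > 0) {
    ord <- 2:3
    wobble <- list(order = ord,
                   cosc = stats::rnorm(length(ord), 0, spec$wobble_amp),
                   sinc = stats::rnorm(length(ord), 0, spec$wobble_amp))
  }

  nt <- spec$n_theta; np <- spec$n_psi
  phi <- -180 + 360 * (seq_len(nt) - 1) / nt
  r2d <- .phantom_radius2d(phi, spec, wobble)
  psi <- pi * seq_len(np - 1) / np          # interior rings
  s <- sin(psi); z <- spec$z_center + spec$c_vert * cos(psi)

  ## ring vertices: (np-1) rings of nt points, then the two poles
  cx <- cos(phi * pi / 180); sy <- sin(phi * pi / 180)
  vid <- function(i, j) (i - 1L) * nt + ((j - 1L) %% nt) + 1L
  verts <- matrix(0, (np - 1) * nt + 2, 3)
  for (i in seq_len(np - 1)) {
    rows <- (i - 1L) * nt + seq_len(nt)
    verts[rows, 1] <- s[i] * r2d * cx
    verts[rows, 2] <- s[i] * r2d * sy
    verts[rows, 3] <- z[i]
  }
  top <- (np - 1L) * nt + 1L
  bot <- top + 1L
  verts[top, ] <- c(0, 0, spec$z_center + spec$c_vert)
  verts[bot, ] <- c(0, 0, spec$z_center - spec$c_vert)

  faces <- vector("list", np)
  ## top fan (ring 1)
  faces[[1]] <- cbind(top, vid(1, seq_len(nt)), vid(1, seq_len(nt) + 1L))
  for (i in seq_len(np - 2)) {
    j <- seq_len(nt)
    faces[[i + 1]] <- rbind(
      cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
      cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L))
    )
  }
  ## bottom fan (last ring)
  faces[[np]] <- cbind(bot, vid(np - 1L, seq_len(nt) + 1L),
                       vid(np - 1L, seq_len(nt)))
  faces <- do.call(rbind, faces)

  if (spec$noise_sd > 0) {
    ## spatially correlated Gaussian radial noise: an i.i.d. per-vertex field
    ## smoothed over the surface lattice (as surface-extraction error is
    ## smooth at the millimetre scale), rescaled to the requested SD
    E <- matrix(stats::rnorm((np - 1) * nt), np - 1, nt)
    for (pass in 1:4) {
      El <- E[, c(nt, seq_len(nt - 1))]; Er <- E[, c(2:nt, 1)]
      Eu <- E[c(1, seq_len(np - 2)), ]; Ed <- E[c(2:(np - 1), np - 1), ]
      E <- (E + El + Er + Eu + Ed) / 5
    }
    E <- E * (spec$noise_sd / stats::sd(E))
    eps <- c(as.vector(t(E)), mean(E[1, ]), mean(E[np - 1, ]))
    center <- c(0, 0, spec$z_center)
    d <- sweep(verts, 2, center)
    len <- sqrt(rowSums(d^2)); len[len == 0] <- 1
    verts <- verts + (d / len) * eps
  }
  .restore_seed(rng)

  surf_pt <- function(phi_deg) {
    psi0 <- acos((0 - spec$z_center) / spec$c_vert)
    s0 <- sin(psi0)
    r <- .phantom_radius2d(phi_deg, spec, wobble) * s0
    c(r * cos(phi_deg * pi / 180), r * sin(phi_deg * pi / 180), 0)
  }
  lms <- landmark_set(
    ex_left = surf_pt(spec$ex_phi), ex_right = surf_pt(-spec$ex_phi),
    po_left = surf_pt(spec$po_phi), po_right = surf_pt(-spec$po_phi)
  )
  structure(list(mesh = tri_mesh(verts, faces), landmarks = lms,
                 label = spec$phenotype, spec = spec),
            class = "cranio_phantom")
}

#' @export
print.cranio_phantom <- function(x, ...) {
  cat(sprintf("cranio_phantom: %s (seed %d, noise %.2g mm)\n",
              x$label, x$spec$seed, x$spec$noise_sd))
  print(x$mesh)
  invisible(x)
}

## run code under a seed without clobbering the caller's RNG state
.with_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Generate a labeled phantom cohort
#'
#' Draws `n_per_group` subjects per phenotype with per-subject parameter
#' jitter: log-normal jitter of the cross-section semi-axes and boss
#' amplitudes, small angular jitter of the plagiocephalic apex deviation,
#' and the phenotype's harmonic wobble. Controls get wider jitter than the
#' synostotic groups, emulating the wide normal variation of head shape
#' against the growth-constrained synostotic shapes. The same seed
#' reproduces the cohort exactly.
#'
#' @param n_per_group subjects per phenotype (>= 0).
#' @param phenotypes labels to include (default all six).
#' @param seed cohort seed.
#' @param noise_sd vertex noise SD in mm for every subject (default 0.3).
#' @param jitter_scale multiplier on all jitter SDs (0 = identical subjects
#'   up to noise).
#' @return list of class `cranio_cohort`: `phantoms` (list of
#'   `cranio_phantom`) and `manifest` (data frame with subject_id, label,
#'   seed and key spec parameters).
#' @export
generate_cohort <- function(n_per_group, phenotypes = phantom_phenotypes(),
                            seed = 1L, noise_sd = 0.3, jitter_scale = 1) {
  if (n_per_group < 0)
    cranio_abort("cranio_spec_error", "n_per_group must be >= 0")
  old <- .with_seed(as.integer(seed))
  on.exit(.restore_seed(old))
  phantoms <- list(); rows <- list()
  for (ph in phenotypes) {
    base <- .phantom_defaults[[ph]]
    sd_ab <- jitter_scale * if (ph == "control") 0.020 else 0.012
    sd_amp <- jitter_scale * if (ph == "control") 0.20 else 0.10
    for (i in seq_len(n_per_group)) {
      sseed <- sample.int(2147483646L, 1)
      ov <- list(
        a = base$a * exp(stats::rnorm(1, 0, sd_ab)),
        b = base$b * exp(stats::rnorm(1, 0, sd_ab)),
        boss_f_amp = base$boss_f_amp * exp(stats::rnorm(1, 0, sd_amp)),
        boss_o_amp = base$boss_o_amp * exp(stats::rnorm(1, 0, sd_amp))
      )
      if (base$flat_amp > 0) {
        ov$flat_amp <- base$flat_amp * exp(stats::rnorm(1, 0, sd_amp))
        ov$apex_dev <- base$apex_dev + stats::rnorm(1, 0, jitter_scale * 2)
      }
      spec <- do.call(phantom_spec, c(
        list(phenotype = ph, noise_sd = noise_sd, seed = sseed,
             wobble_amp = base$wobble_amp * jitter_scale), ov))
      id <- sprintf("%s_%02d", ph, i)
      phantoms[[id]] <- generate_phantom(spec)
      rows[[id]] <- data.frame(
        subject_id = id, label = ph, seed = sseed,
        a = spec$a, b = spec$b, noise_sd = noise_sd,
        wobble_amp = spec$wobble_amp, stringsAsFactors = FALSE)
    }
  }
  structure(list(phantoms = phantoms,
                 manifest = do.call(rbind, c(rows, list(make.row.names = FALSE)))),
            class = "cranio_cohort")
}

#' @export
print.cranio_cohort <- function(x, ...) {
  cat(sprintf("cranio_cohort: %d phantoms\n", length(x$phantoms)))
  if (length(x$phantoms)) print(table(x$manifest$label))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One mesh (STL) and one landmark JSON per subject, plus the manifest CSV.
#'
#' @param cohort a `cranio_cohort`.
#' @param dir output directory (created if needed).
#' @param format mesh format, `"stl"`, `"obj"` or `"ply"`.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = "stl") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$phantoms)) {
    ph <- cohort$phantoms[[id]]
    write_mesh(ph$mesh, file.path(dir, paste0(id, ".", format)))
    write_landmarks(ph$landmarks, file.path(dir, paste0(id, "_landmarks.json")))
  }
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(cohort$manifest, mf, row.names = FALSE)
  invisible(mf)
}
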