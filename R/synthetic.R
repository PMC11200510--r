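## Zoned digital prostate phantoms: class-conditional IVIM tissue parameters,
## ellipse CZ/PZ geometry, spherical lesions, Rician noise.

#' Tissue class with truncated-normal IVIM parameter distribution
#'
#' @slot name One of `"PCa-lesion"`, `"BPH-lesion"`, `"benign-CZ"`,
#'   `"benign-PZ"`, `"background"`.
#' @slot dist data.frame with rows `s0`, `f`, `d`, `dstar` and columns
#'   `mean`, `sd`, `lo`, `hi`. Bounds must keep every draw a valid
#'   [IVIMParams-class]; in particular `d$hi <= dstar$lo` so D <= D* holds
#'   for any pair of truncated draws.
#' @export
setClass("TissueClass",
  representation(name = "character", dist = "data.frame"),
  validity = function(object) {
    okNames <- c("PCa-lesion", "BPH-lesion", "benign-CZ", "benign-PZ",
                 "background")
    if (!object@name %in% okNames)
      return(sprintf("unknown tissue class '%s'", object@name))
    d <- object@dist
    if (!identical(rownames(d), c("s0", "f", "d", "dstar")) ||
        !all(c("mean", "sd", "lo", "hi") %in% colnames(d)))
      return("dist must have rows s0,f,d,dstar and columns mean,sd,lo,hi")
    if (any(!is.finite(as.matrix(d)))) return("distribution parameters must be finite")
    if (any(d$sd < 0)) return("sd must be >= 0")
    if (any(d$lo > d$hi)) return("lower bounds must not exceed upper bounds")
    if (d["f", "lo"] < 0 || d["f", "hi"] > 1) return("f bounds must lie in [0, 1]")
    if (d["s0", "lo"] <= 0) return("S0 lower bound must be > 0")
    if (d["d", "lo"] <= 0) return("D lower bound must be > 0")
    if (d["d", "hi"] > d["dstar", "lo"])
      return("D upper bound must not exceed D* lower bound (ensures D <= D*)")
    TRUE
  })

tissueClass <- function(name, s0, f, d, dstar) {
  dist <- as.data.frame(rbind(s0 = s0, f = f, d = d, dstar = dstar))
  colnames(dist) <- c("mean", "sd", "lo", "hi")
  new("TissueClass", name = name, dist = dist)
}

#' Default tissue parameter distributions
#'
#' Physiologically plausible, partially overlapping IVIM parameter ranges for
#' the five phantom tissue classes. Tumour tissue (high cellularity) has the
#' lowest diffusion coefficient (D about 0.8e-3 mm^2/s) and an elevated
#' perfusion fraction; benign peripheral zone the highest D (about
#' 1.6e-3 mm^2/s); BPH nodules sit between (about 1.2e-3 mm^2/s), so the
#' classes are separable but not trivially so.
#'
#' @return Named list of [TissueClass-class] objects.
#' @export
defaultTissueClasses <- function() {
  list(
    `benign-PZ`  = tissueClass("benign-PZ",
      s0 = c(1000, 100, 600, 1400), f = c(0.12, 0.04, 0.05, 0.25),
      d = c(1.6e-3, 0.15e-3, 1.0e-3, 2.2e-3), dstar = c(12e-3, 4e-3, 5e-3, 30e-3)),
    `benign-CZ`  = tissueClass("benign-CZ",
      s0 = c(1000, 100, 600, 1400), f = c(0.10, 0.03, 0.05, 0.25),
      d = c(1.3e-3, 0.15e-3, 0.8e-3, 1.9e-3), dstar = c(10e-3, 3e-3, 5e-3, 30e-3)),
    `PCa-lesion` = tissueClass("PCa-lesion",
      s0 = c(1100, 100, 600, 1500), f = c(0.18, 0.05, 0.05, 0.35),
      d = c(0.8e-3, 0.12e-3, 0.4e-3, 1.2e-3), dstar = c(15e-3, 5e-3, 5e-3, 30e-3)),
    `BPH-lesion` = tissueClass("BPH-lesion",
      s0 = c(1050, 100, 600, 1500), f = c(0.14, 0.04, 0.05, 0.30),
      d = c(1.2e-3, 0.12e-3, 0.8e-3, 1.7e-3), dstar = c(12e-3, 4e-3, 5e-3, 30e-3)),
    background   = tissueClass("background",
      s0 = c(300, 50, 100, 600), f = c(0.05, 0.02, 0.0, 0.15),
      d = c(2.0e-3, 0.3e-3, 1.0e-3, 3.0e-3), dstar = c(8e-3, 2e-3, 4e-3, 20e-3))
  )
}

#' Sample IVIM parameters from a tissue class
#'
#' Truncated-normal sampling: each parameter is redrawn until it lies within
#' its `[lo, hi]` bounds, so every returned quadruple is a valid
#' [IVIMParams-class]. With all `sd = 0` the distribution means are returned
#' exactly.
#'
#' @param tissue A [TissueClass-class].
#' @param n Number of draws.
#' @return For `n = 1` an [IVIMParams-class]; otherwise an `n x 4` matrix
#'   with columns `s0, f, d, dstar`.
#' @export
sampleTissueParams <- function(tissue, n = 1L) {
  stopifnot(is(tissue, "TissueClass"))
  validObject(tissue)
  d <- tissue@dist
  draw <- function(row) {
    m <- d[row, "mean"]; s <- d[row, "sd"]
    lo <- d[row, "lo"]; hi <- d[row, "hi"]
    if (s == 0) return(rep(min(max(m, lo), hi), n))
    out <- rnorm(n, m, s)
    bad <- which(out < lo | out > hi)
    guard <- 0L
    while (length(bad) > 0L && guard < 1000L) {
      out[bad] <- rnorm(length(bad), m, s)
      bad <- bad[out[bad] < lo | out[bad] > hi]
      guard <- guard + 1L
    }
    out[out < lo] <- lo; out[out > hi] <- hi
    out
  }
  mat <- cbind(s0 = draw("s0"), f = draw("f"), d = draw("d"),
               dstar = draw("dstar"))
  if (n == 1L) ivimParams(mat[1, 1], mat[1, 2], mat[1, 3], mat[1, 4]) else mat
}

#' Phantom cohort specification
#'
#' @slot cohortSize,nPositive Number of cases and number labelled PCa.
#' @slot gridShape Integer (nx, ny, nz), in-plane dimensions >= 8.
#' @slot voxelSpacing Per-axis spacing, mm.
#' @slot bvalues Acquisition b-value series.
#' @slot tissueClasses Named list of [TissueClass-class] objects (must cover
#'   the five default names).
#' @slot noiseSigma Rician noise scale, signal units (SNR = S0 / sigma).
#' @slot lesionRadius In-plane lesion radius, voxels.
#' @slot pzLesionProb Probability the lesion is placed in the PZ (else CZ).
#' @slot seed Master seed; case i uses seed + i.
#' @export
setClass("PhantomSpec",
  representation(cohortSize = "integer", nPositive = "integer",
                 gridShape = "integer", voxelSpacing = "numeric",
                 bvalues = "numeric", tissueClasses = "list",
                 noiseSigma = "numeric", lesionRadius = "numeric",
                 pzLesionProb = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@cohortSize < 1L) return("cohortSize must be >= 1")
    if (object@nPositive < 0L || object@nPositive > object@cohortSize)
      return("nPositive must lie in [0, cohortSize]")
    if (length(object@gridShape) != 3L || any(object@gridShape[1:2] < 8L))
      return("grid dimensions must be >= 8 in-plane")
    if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
    ok <- tryCatch({ checkBValues(object@bvalues); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) return(ok)
    need <- c("PCa-lesion", "BPH-lesion", "benign-CZ", "benign-PZ", "background")
    if (!all(need %in% names(object@tissueClasses)))
      return("tissueClasses must name all five default classes")
    if (object@pzLesionProb < 0 || object@pzLesionProb > 1)
      return("pzLesionProb must lie in [0, 1]")
    if (object@lesionRadius < 1) return("lesionRadius must be >= 1 voxel")
    TRUE
  })

#' Construct a [PhantomSpec-class] with the study defaults
#'
#' Defaults emulate the study conditions: an 80-case cohort with 37 PCa and
#' 43 BPH cases, the 9-point b-value grid 0-1400 s/mm^2, a 64x64x8 voxel
#' grid, Rician noise sigma 20 (SNR 50 at S0 = 1000), spherical lesions of
#' 4-voxel radius placed in the PZ with probability 0.7.
#'
#' @param cohortSize,nPositive,gridShape,voxelSpacing,bvalues,tissueClasses,noiseSigma,lesionRadius,pzLesionProb,seed
#'   Override any default; see [PhantomSpec-class].
#' @return A `PhantomSpec`.
#' @export
phantomSpec <- function(cohortSize = 80L, nPositive = 37L,
                        gridShape = c(64L, 64L, 8L),
                        voxelSpacing = c(3, 3, 3.5),
                        bvalues = defaultBValues(),
                        tissueClasses = defaultTissueClasses(),
                        noiseSigma = 20, lesionRadius = 4,
                        pzLesionProb = 0.7, seed = 1L) {
  new("PhantomSpec", cohortSize = as.integer(cohortSize),
      nPositive = as.integer(nPositive), gridShape = as.integer(gridShape),
      voxelSpacing = as.numeric(voxelSpacing), bvalues = as.numeric(bvalues),
      tissueClasses = tissueClasses, noiseSigma = noiseSigma,
      lesionRadius = lesionRadius, pzLesionProb = pzLesionProb,
      seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %d cases (%d PCa / %d BPH), grid %s, sigma = %g, seed = %d\n",
    object@cohortSize, object@nPositive, object@cohortSize - object@nPositive,
    paste(object@gridShape, collapse = "x"), object@noiseSigma, object@seed))
})

#' One simulated case
#'
#' @slot dwi Noisy [DWIVolume-class].
#' @slot masks [ZoneMaskSet-class].
#' @slot truth Ground-truth [ParameterMaps-class].
#' @slot label `"PCa"` or `"BPH"`.
#' @slot caseId Unique identifier.
#' @export
setClass("PhantomCase",
  representation(dwi = "DWIVolume", masks = "ZoneMaskSet",
                 truth = "ParameterMaps", label = "character",
                 caseId = "character"),
  validity = function(object) {
    if (!object@label %in% c("PCa", "BPH")) return("label must be PCa or BPH")
    TRUE
  })

setMethod("show", "PhantomCase", function(object) {
  cat(sprintf("PhantomCase %s [%s]\n", object@caseId, object@label))
  show(object@dwi)
  show(object@masks)
})

## Ellipse zone geometry: CZ is an inner ellipse, PZ the surrounding shell,
## replicated over slices (2D multi-slice phantom).
zoneGeometry <- function(gridShape) {
  nx <- gridShape[1]; ny <- gridShape[2]; nz <- gridShape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  ax <- 0.38 * nx; ay <- 0.30 * ny
  xg <- matrix(seq_len(nx), nx, ny)
  yg <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  ell <- function(sx, sy) ((xg - cx) / sx)^2 + ((yg - cy) / sy)^2 <= 1
  prost2d <- ell(ax, ay)
  cz2d <- ell(0.55 * ax, 0.55 * ay)
  pz2d <- prost2d & !cz2d
  rep3d <- function(m) array(m, dim = c(nx, ny, nz))
  list(prostate = rep3d(prost2d), cz = rep3d(cz2d), pz = rep3d(pz2d))
}

## Place a spherical (in-plane circular, z-scaled) lesion inside a zone.
placeLesion <- function(zoneMask, radius, spacing) {
  shape <- dim(zoneMask)
  rz <- max(1, radius * spacing[1] / spacing[3])
  cand <- which(zoneMask)
  if (length(cand) == 0L) stop("lesion zone is empty")
  rr <- (-ceiling(radius)):ceiling(radius)
  zz <- ((-ceiling(rz)):ceiling(rz))^2 * (radius / rz)^2
  sphereVol <- sum(outer(outer(rr^2, rr^2, `+`), zz, `+`) <= radius^2)
  for (try in seq_len(20L)) {
    ctr <- arrayInd(sample(cand, 1L), shape)
    xg <- (seq_len(shape[1]) - ctr[1])^2
    yg <- (seq_len(shape[2]) - ctr[2])^2
    zg <- ((seq_len(shape[3]) - ctr[3]) * (radius / rz))^2
    d2 <- outer(outer(xg, yg, `+`), zg, `+`)
    lesion <- d2 <= radius^2 & zoneMask
    if (sum(lesion) >= 0.3 * sphereVol) return(lesion)
  }
  stop("lesion radius exceeds the zone extent: could not place the lesion")
}

#' Add Rician noise to magnitude DWI data
#'
#' Each intensity s becomes `sqrt((s + n1)^2 + n2^2)` with independent
#' zero-mean Gaussian `n1`, `n2` of scale `sigma` - the magnitude-MRI noise
#' model. Output is non-negative everywhere; `sigma = 0` returns the input
#' unchanged.
#'
#' @param dwi A [DWIVolume-class] or numeric array.
#' @param sigma Noise scale, signal units (>= 0).
#' @return Same type as `dwi`.
#' @export
addRicianNoise <- function(dwi, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (is(dwi, "DWIVolume")) {
    out <- dwi
    out@intensities <- addRicianNoise(dwi@intensities, sigma)
    return(out)
  }
  if (sigma == 0) return(dwi)
  n <- length(dwi)
  noisy <- sqrt((dwi + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  if (is.array(dwi)) array(noisy, dim = dim(dwi)) else noisy
}

#' Build one zoned phantom case
#'
#' Constructs the ellipse CZ/PZ geometry, places a spherical lesion in the PZ
#' with probability `pzLesionProb` (else CZ), samples per-voxel ground-truth
#' IVIM parameters from the tissue classes (`PCa-lesion` or `BPH-lesion`
#' according to `label`), evaluates the noiseless bi-exponential signal at
#' every b-value and adds Rician noise.
#'
#' @param spec A [PhantomSpec-class].
#' @param label `"PCa"` or `"BPH"`.
#' @param caseSeed Integer seed for this case's randomness.
#' @param caseId Identifier string.
#' @return A [PhantomCase-class].
#' @export
buildPhantom <- function(spec, label = c("PCa", "BPH"),
                         caseSeed = spec@seed, caseId = "case_001") {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  label <- match.arg(label)
  set.seed(caseSeed)

  shape <- spec@gridShape
  geo <- zoneGeometry(shape)
  inPZ <- runif(1) < spec@pzLesionProb
  zone <- if (inPZ) geo$pz else geo$cz
  lesion <- placeLesion(zone, spec@lesionRadius, spec@voxelSpacing)
  masks <- zoneMaskSet(geo$prostate, geo$cz, geo$pz, lesion)

  lesionClass <- if (label == "PCa") "PCa-lesion" else "BPH-lesion"
  regions <- list(
    list(mask = !geo$prostate, class = "background"),
    list(mask = geo$cz & !lesion, class = "benign-CZ"),
    list(mask = geo$pz & !lesion, class = "benign-PZ"),
    list(mask = lesion, class = lesionClass))

  blank <- array(NA_real_, dim = shape)
  s0 <- f <- d <- dstar <- blank
  for (rg in regions) {
    idx <- which(rg$mask)
    if (length(idx) == 0L) next
    draws <- sampleTissueParams(spec@tissueClasses[[rg$class]], n = length(idx))
    if (length(idx) == 1L) draws <- matrix(draws, nrow = 1)
    s0[idx] <- draws[, 1]; f[idx] <- draws[, 2]
    d[idx] <- draws[, 3]; dstar[idx] <- draws[, 4]
  }

  nb <- length(spec@bvalues)
  noiseless <- array(0, dim = c(shape, nb))
  for (j in seq_len(nb)) {
    b <- spec@bvalues[j]
    noiseless[, , , j] <- s0 * (f * exp(-b * dstar) + (1 - f) * exp(-b * d))
  }

  bT <- max(spec@bvalues)
  adcTruth <- -log(pmax(noiseless[, , , nb], 1e-6 * s0) / s0) / bT
  status <- array("converged", dim = shape)
  truth <- parameterMaps(s0, f, d, dstar, array(adcTruth, dim = shape), status)

  noisy <- addRicianNoise(noiseless, spec@noiseSigma)
  dwi <- dwiVolume(noisy, spec@bvalues, spec@voxelSpacing)
  new("PhantomCase", dwi = dwi, masks = masks, truth = truth,
      label = label, caseId = caseId)
}

#' Generate a labelled phantom cohort
#'
#' Produces exactly `nPositive` PCa and `cohortSize - nPositive` BPH cases.
#' The label order is shuffled deterministically from the master seed and
#' case i is built with seed `spec@seed + i`, so identical specs give
#' byte-identical cohorts.
#'
#' @param spec A [PhantomSpec-class].
#' @return List of [PhantomCase-class] objects with unique case ids.
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  set.seed(spec@seed)
  labels <- sample(c(rep("PCa", spec@nPositive),
                     rep("BPH", spec@cohortSize - spec@nPositive)))
  lapply(seq_len(spec@cohortSize), function(i) {
    buildPhantom(spec, labels[i], caseSeed = spec@seed + i,
                 caseId = sprintf("case_%03d", i))
  })
}
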