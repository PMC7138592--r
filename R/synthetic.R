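#' PhantomSpec: parameters of the synthetic cohort generator
#'
#' Describes a phantom cohort: a desk-scale labelled "white matter" atlas of
#' boxes inside an ellipsoidal brain, periventricular lesions whose
#' per-subject volume scales with age, two structural channels (FLAIR-like
#' hyperintense / T1-like hypointense lesions), optional diffusion metric
#' channels degraded inside lesions, and cognitive scores generated as noisy
#' linear functions of regional lesion load.
#'
#' @slot gridShape integer(3) array dimensions.
#' @slot voxelSize numeric(3) voxel pitch in mm.
#' @slot nSubjects number of subjects.
#' @slot atlasSpec list with elements \code{wm} (data.frame of labelled
#'   white-matter boxes: name, hemisphere, x0..z1 as grid fractions,
#'   half-open), \code{ventricle} (data.frame of boxes forming the ventricle
#'   structure), \code{cerebellum} (one-row data.frame, the exclusion
#'   region) and \code{brain} (list center/radii fractions of the brain
#'   ellipsoid).
#' @slot lesionModel list: \code{baseRate} (multiplier on expected lesion
#'   volume), \code{decayMm} (periventricular decay length of the lesion
#'   probability field, mm), \code{meanLogVolMl}, \code{sdLogVolMl}
#'   (log-normal per-subject volume scale), \code{ageSlope} (slope of
#'   log-volume on age, per year), \code{blobSizeVoxels} (mean voxels per
#'   lesion blob), \code{minVolMl}, \code{maxVolMl} (clipping range).
#' @slot intensityModel per-channel tissue means/SDs and lesion contrast;
#'   the FLAIR-like contrast must be positive and the T1-like negative.
#' @slot scoreModel named list, one entry per test:
#'   \code{list(intercept, beta, noiseSd)} with \code{beta} a named vector
#'   over atlas region names (mm^-3 of lesion load).
#' @slot dtiModel per-metric (fa, md, ad, rd) \code{list(healthyMean,
#'   csfMean, lesionDelta, noiseSd)}; FA decreases inside lesions, the
#'   diffusivities increase.
#' @slot covariateModel list: ageMin, ageMax (years), femaleProb,
#'   educationMean, educationSd (years).
#' @slot includeDti logical, generate fa/md/ad/rd channels.
#' @slot seed integer seed making generation deterministic.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSize = "numeric",
                 nSubjects = "integer", atlasSpec = "list",
                 lesionModel = "list", intensityModel = "list",
                 scoreModel = "list", dtiModel = "list",
                 covariateModel = "list", includeDti = "logical",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
    msg <- c(msg, "gridShape must be 3 values, each >= 8")
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  im <- object@intensityModel
  if (!is.null(im$flair) && im$flair$lesionContrast <= 0)
    msg <- c(msg, "lesion contrast must be positive on the FLAIR-like channel")
  if (!is.null(im$t1) && im$t1$lesionContrast >= 0)
    msg <- c(msg, "lesion contrast must be negative on the T1-like channel")
  if (length(object@scoreModel) < 1L)
    msg <- c(msg, "scoreModel must define at least one test")
  regions <- regionFullNames(object@atlasSpec$wm)
  for (tn in names(object@scoreModel)) {
    b <- object@scoreModel[[tn]]$beta
    if (length(b) && !all(names(b) %in% regions))
      msg <- c(msg, sprintf("beta for %s names unknown regions", tn))
  }
  if (object@lesionModel$decayMm <= 0)
    msg <- c(msg, "decayMm must be positive")
  if (length(msg)) msg else TRUE
})

regionFullNames <- function(wm) {
  ifelse(wm$hemisphere == "none", wm$name, paste(wm$name, wm$hemisphere))
}

#' Default desk-scale atlas geometry
#'
#' Twelve white-matter boxes (six structures x two hemispheres) arranged
#' around two periventricular boxes inside an ellipsoidal brain, with a
#' posterior-inferior cerebellum exclusion box. All coordinates are grid
#' fractions; intervals are half-open so neighbouring boxes do not overlap.
#'
#' @return list with elements \code{wm}, \code{ventricle}, \code{cerebellum},
#'   \code{brain} (see \linkS4class{PhantomSpec}).
#' @export
defaultAtlasSpec <- function() {
  box <- function(name, hemi, x0, x1, y0, y1, z0, z1)
    data.frame(name = name, hemisphere = hemi, x0 = x0, x1 = x1,
               y0 = y0, y1 = y1, z0 = z0, z1 = z1,
               stringsAsFactors = FALSE)
  # each region type keeps comparable contact with the ventricle box so
  # lesion prevalence is balanced across the atlas (L boxes given; R boxes
  # mirrored in x)
  mirror <- function(df) { x0 <- 1 - df$x1; df$x1 <- 1 - df$x0; df$x0 <- x0
                           df$hemisphere <- "R"; df }
  lhs <- rbind(
    box("Tapetum",                          "L", 0.26, 0.36, 0.30, 0.48, 0.44, 0.62),
    box("Anterior corona radiata",          "L", 0.26, 0.36, 0.52, 0.70, 0.44, 0.62),
    box("Posterior corona radiata",         "L", 0.28, 0.44, 0.12, 0.30, 0.44, 0.64),
    box("Anterior limb of internal capsule","L", 0.28, 0.44, 0.70, 0.88, 0.44, 0.64),
    box("Posterior thalamic radiation",     "L", 0.30, 0.46, 0.26, 0.48, 0.30, 0.44),
    box("Superior longitudinal fasciculus", "L", 0.24, 0.40, 0.34, 0.66, 0.62, 0.80))
  wm <- rbind(lhs, mirror(lhs))
  wm <- wm[order(wm$name, wm$hemisphere), ]
  rownames(wm) <- NULL
  ventricle <- rbind(
    box("Ventricle", "L", 0.36, 0.46, 0.30, 0.70, 0.46, 0.60),
    box("Ventricle", "R", 0.54, 0.64, 0.30, 0.70, 0.46, 0.60))
  cerebellum <- box("Cerebellum", "none", 0.32, 0.68, 0.10, 0.32, 0.12, 0.36)
  brain <- list(center = c(0.50, 0.50, 0.52), radii = c(0.44, 0.46, 0.42))
  list(wm = wm, ventricle = ventricle, cerebellum = cerebellum, brain = brain)
}

#' Construct a PhantomSpec
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: a 48x56x48 grid at 2 mm isotropic, 20 subjects aged 62-80 whose
#' log lesion volume increases with age (volumes spanning roughly 1-40 ml),
#' strongly hyperintense FLAIR-like lesions, and two score columns -- an
#' MMSE-like test declining with posterior lesion load and a TRAILB-like
#' test increasing with it, both driven by the right tapetum and right
#' posterior corona radiata.
#'
#' @param gridShape,voxelSize,nSubjects,atlasSpec,lesionModel,intensityModel
#'   see \linkS4class{PhantomSpec}; any omitted element of a list argument
#'   falls back to its default.
#' @param scoreModel,dtiModel,covariateModel,includeDti,seed idem.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(gridShape = c(48L, 56L, 48L), voxelSize = c(2, 2, 2),
                        nSubjects = 20L, atlasSpec = defaultAtlasSpec(),
                        lesionModel = list(), intensityModel = list(),
                        scoreModel = NULL, dtiModel = list(),
                        covariateModel = list(), includeDti = TRUE,
                        seed = 1L) {
  lm_def <- list(baseRate = 1, decayMm = 6, meanLogVolMl = log(6),
                 sdLogVolMl = 0.7, ageSlope = 0.055, blobSizeVoxels = 350,
                 minVolMl = 0.5, maxVolMl = 45)
  im_def <- list(
    t1    = list(wmMean = 100, csfMean = 30, noiseSd = 2.5, lesionContrast = -50),
    flair = list(wmMean = 110, csfMean = 40, noiseSd = 3, lesionContrast = 90))
  dti_def <- list(
    fa = list(healthyMean = 0.45,    csfMean = 0.05,  lesionDelta = -0.06,    noiseSd = 0.04),
    md = list(healthyMean = 7.5e-4,  csfMean = 3e-3,  lesionDelta = 1.2e-4,   noiseSd = 6e-5),
    ad = list(healthyMean = 1.2e-3,  csfMean = 3e-3,  lesionDelta = 2.0e-4,   noiseSd = 5e-5),
    rd = list(healthyMean = 5.5e-4,  csfMean = 3e-3,  lesionDelta = 1.5e-4,   noiseSd = 5e-5))
  cv_def <- list(ageMin = 62, ageMax = 80, femaleProb = 0.464,
                 educationMean = 14.89, educationSd = 1.20)
  if (is.null(scoreModel))
    scoreModel <- list(
      MMSE = list(intercept = 28.4, noiseSd = 0.8,
                  beta = c("Tapetum R" = -0.008,
                           "Posterior corona radiata R" = -0.008)),
      TRAILB = list(intercept = 88, noiseSd = 5,
                    beta = c("Tapetum R" = 0.05,
                             "Posterior corona radiata R" = 0.05)))
  merge_def <- function(user, def) { def[names(user)] <- user; def }
  new("PhantomSpec",
      gridShape = as.integer(gridShape), voxelSize = as.numeric(voxelSize),
      nSubjects = as.integer(nSubjects), atlasSpec = atlasSpec,
      lesionModel = merge_def(lesionModel, lm_def),
      intensityModel = merge_def(intensityModel, im_def),
      scoreModel = scoreModel,
      dtiModel = merge_def(dtiModel, dti_def),
      covariateModel = merge_def(covariateModel, cv_def),
      includeDti = includeDti, seed = as.integer(seed))
}

# voxel-center coordinates (mm) for every voxel of a grid, as an nvox x 3
# matrix in array order; 0-based indices offset by half a voxel.
voxelCentersMm <- function(gridShape, voxelSize) {
  xs <- (seq_len(gridShape[1]) - 0.5) * voxelSize[1]
  ys <- (seq_len(gridShape[2]) - 0.5) * voxelSize[2]
  zs <- (seq_len(gridShape[3]) - 0.5) * voxelSize[3]
  cbind(rep(xs, times = gridShape[2] * gridShape[3]),
        rep(rep(ys, each = gridShape[1]), times = gridShape[3]),
        rep(zs, each = gridShape[1] * gridShape[2]))
}

# logical voxel membership of a half-open fractional box
boxMask <- function(gridShape, row) {
  fx <- (seq_len(gridShape[1]) - 0.5) / gridShape[1]
  fy <- (seq_len(gridShape[2]) - 0.5) / gridShape[2]
  fz <- (seq_len(gridShape[3]) - 0.5) / gridShape[3]
  inx <- fx >= row$x0 & fx < row$x1
  iny <- fy >= row$y0 & fy < row$y1
  inz <- fz >= row$z0 & fz < row$z1
  outer(outer(inx, iny), inz)
}

ellipsoidMask <- function(gridShape, center, radii) {
  fx <- (seq_len(gridShape[1]) - 0.5) / gridShape[1]
  fy <- (seq_len(gridShape[2]) - 0.5) / gridShape[2]
  fz <- (seq_len(gridShape[3]) - 0.5) / gridShape[3]
  dx2 <- ((fx - center[1]) / radii[1])^2
  dy2 <- ((fy - center[2]) / radii[2])^2
  dz2 <- ((fz - center[3]) / radii[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

# exact mm distance from every voxel center to the nearest point of a union
# of axis-aligned fractional boxes
distToBoxesMm <- function(gridShape, voxelSize, boxes) {
  ctr <- voxelCentersMm(gridShape, voxelSize)
  d <- rep(Inf, nrow(ctr))
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    lo <- c(b$x0 * gridShape[1], b$y0 * gridShape[2], b$z0 * gridShape[3]) * voxelSize
    hi <- c(b$x1 * gridShape[1], b$y1 * gridShape[2], b$z1 * gridShape[3]) * voxelSize
    dx <- pmax(lo[1] - ctr[, 1], ctr[, 1] - hi[1], 0)
    dy <- pmax(lo[2] - ctr[, 2], ctr[, 2] - hi[2], 0)
    dz <- pmax(lo[3] - ctr[, 3], ctr[, 3] - hi[3], 0)
    d <- pmin(d, sqrt(dx^2 + dy^2 + dz^2))
  }
  d
}

#' Periventricular lesion probability field of a phantom spec
#'
#' The spatial field lesion seeds and growth are sampled from: proportional
#' to exp(-d / decayMm) where d is the mm distance to the ventricle
#' structure, restricted to eligible voxels (in-brain, outside ventricle and
#' cerebellum).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list: \code{field} (Volume, 0 outside eligible voxels),
#'   \code{distanceMm} (Volume), \code{eligible} (binary Volume).
#' @export
lesionProbabilityField <- function(spec) {
  g <- spec@gridShape
  geo <- phantomGeometry(spec)
  d <- distToBoxesMm(g, spec@voxelSize, spec@atlasSpec$ventricle)
  p <- exp(-d / spec@lesionModel$decayMm)
  p[!geo$eligible] <- 0
  vol <- function(x) Volume(array(as.numeric(x), g), spec@voxelSize, "phantom")
  list(field = vol(p), distanceMm = vol(d), eligible = vol(geo$eligible))
}

# masks and atlas labels implied by the geometry of a spec
phantomGeometry <- function(spec) {
  g <- spec@gridShape
  as_ <- spec@atlasSpec
  brain <- ellipsoidMask(g, as_$brain$center, as_$brain$radii)
  vent <- array(FALSE, g)
  for (i in seq_len(nrow(as_$ventricle)))
    vent <- vent | boxMask(g, as_$ventricle[i, ])
  cereb <- boxMask(g, as_$cerebellum) & brain
  vent <- vent & brain
  labels <- array(0L, g)
  for (i in seq_len(nrow(as_$wm))) {
    m <- boxMask(g, as_$wm[i, ]) & brain & !vent & !cereb & labels == 0L
    if (!any(m))
      stop(sprintf("degenerate atlas spec: region '%s' has zero volume",
                   regionFullNames(as_$wm)[i]))
    labels[m] <- i
  }
  eligible <- brain & !vent & !cereb
  list(brain = brain, ventricle = vent, cerebellum = cereb,
       labels = labels, eligible = eligible)
}

# grow one subject's lesion mask: seeds sampled from the periventricular
# field, then stochastic frontier dilation weighted by the same field until
# the voxel budget is reached. Returns 1-based linear voxel indices.
growLesions <- function(nTarget, fieldP, eligible, gridShape, blobSize) {
  nvox <- length(fieldP)
  nx <- gridShape[1]; ny <- gridShape[2]; nz <- gridShape[3]
  elig_idx <- which(eligible & fieldP > 0)
  if (nTarget < 1L) return(integer(0))
  nBlobs <- max(1L, as.integer(round(nTarget / blobSize)))
  seeds <- sample(elig_idx, min(nBlobs, length(elig_idx)),
                  prob = fieldP[elig_idx])
  inBlob <- logical(nvox); inFront <- logical(nvox)
  inBlob[seeds] <- TRUE
  blob <- seeds
  neighbors <- function(i) {
    i0 <- i - 1L
    x <- i0 %% nx; y <- (i0 %/% nx) %% ny; z <- i0 %/% (nx * ny)
    nb <- c(if (x > 0L) i - 1L, if (x < nx - 1L) i + 1L,
            if (y > 0L) i - nx, if (y < ny - 1L) i + nx,
            if (z > 0L) i - nx * ny, if (z < nz - 1L) i + nx * ny)
    nb
  }
  front <- integer(0)
  for (s in seeds) {
    nb <- neighbors(s)
    nb <- nb[eligible[nb] & !inBlob[nb] & !inFront[nb]]
    inFront[nb] <- TRUE
    front <- c(front, nb)
  }
  while (length(blob) < nTarget && length(front) > 0L) {
    w <- fieldP[front]
    j <- if (length(front) == 1L) 1L else
      sample.int(length(front), 1L, prob = w)
    v <- front[j]
    front[j] <- front[length(front)]
    front <- front[-length(front)]
    inFront[v] <- FALSE
    inBlob[v] <- TRUE
    blob <- c(blob, v)
    nb <- neighbors(v)
    nb <- nb[eligible[nb] & !inBlob[nb] & !inFront[nb]]
    inFront[nb] <- TRUE
    front <- c(front, nb)
  }
  blob
}

#' Generate a phantom cohort
#'
#' Deterministic given \code{spec@seed}. Lesion masks are connected blobs
#' sampled from a probability field that decays with distance to the
#' ventricle structure, scaled so per-subject lesion volume is log-normal
#' and increases with age. The FLAIR-like channel is hyperintense and the
#' T1-like channel hypointense inside lesions; diffusion channels shift
#' inside lesions (FA down, MD/AD/RD up). Scores are
#' \eqn{s_j = intercept_j + \sum_r \beta_{jr} load_r + \epsilon} with
#' \eqn{load_r} the lesion voxel count in region r times the voxel volume
#' in mm^3.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A \linkS4class{Cohort}; each subject carries its true lesion mask.
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  g <- spec@gridShape
  vs <- spec@voxelSize
  voxVol <- prod(vs)
  geo <- phantomGeometry(spec)
  d <- distToBoxesMm(g, vs, spec@atlasSpec$ventricle)
  fieldP <- exp(-d / spec@lesionModel$decayMm)
  fieldP[!geo$eligible] <- 0
  wm <- spec@atlasSpec$wm
  rnames <- regionFullNames(wm)
  lm_ <- spec@lesionModel
  cvm <- spec@covariateModel
  vol <- function(x) Volume(array(as.numeric(x), g), vs, "phantom")

  subjects <- with_seed(spec@seed, {
    lapply(seq_len(spec@nSubjects), function(i) {
      age <- runif(1, cvm$ageMin, cvm$ageMax)
      sex <- if (runif(1) < cvm$femaleProb) "F" else "M"
      education <- rnorm(1, cvm$educationMean, cvm$educationSd)
      midAge <- (cvm$ageMin + cvm$ageMax) / 2
      logV <- log(lm_$baseRate) + lm_$meanLogVolMl +
        lm_$ageSlope * (age - midAge) + rnorm(1, 0, lm_$sdLogVolMl)
      vml <- min(max(exp(logV), lm_$minVolMl), lm_$maxVolMl)
      nTarget <- max(1L, as.integer(round(vml * 1000 / voxVol)))
      lesIdx <- growLesions(nTarget, fieldP, geo$eligible, g,
                            lm_$blobSizeVoxels)
      les <- array(0, g); les[lesIdx] <- 1

      mkChannel <- function(p) {
        a <- array(0, g)
        a[geo$brain] <- p$wmMean
        a[geo$ventricle] <- p$csfMean
        a[lesIdx] <- a[lesIdx] + p$lesionContrast
        a[geo$brain] <- a[geo$brain] + rnorm(sum(geo$brain), 0, p$noiseSd)
        a
      }
      channels <- list(t1 = vol(mkChannel(spec@intensityModel$t1)),
                       flair = vol(mkChannel(spec@intensityModel$flair)))
      if (spec@includeDti) {
        for (m in names(spec@dtiModel)) {
          p <- spec@dtiModel[[m]]
          channels[[m]] <- vol(mkChannel(list(
            wmMean = p$healthyMean, csfMean = p$csfMean,
            lesionContrast = p$lesionDelta, noiseSd = p$noiseSd)))
        }
      }
      loads <- tabulate(geo$labels[lesIdx], nbins = nrow(wm)) * voxVol
      names(loads) <- rnames
      sc <- vapply(spec@scoreModel, function(sm) {
        b <- rep(0, length(rnames)); names(b) <- rnames
        b[names(sm$beta)] <- sm$beta
        sm$intercept + sum(b * loads) + rnorm(1, 0, sm$noiseSd)
      }, numeric(1))
      SubjectRecord(subjectId = sprintf("sub-%03d", i),
                    channels = channels, scores = sc,
                    covariates = list(age = age, sex = sex,
                                      education = education),
                    trueLesionMask = vol(les))
    })
  })

  labnames <- rnames; names(labnames) <- as.character(seq_len(nrow(wm)))
  hemis <- wm$hemisphere; names(hemis) <- names(labnames)
  atlas <- AtlasLabelMap(vol(geo$labels), labnames, hemis)
  Cohort(subjects = subjects, atlas = atlas,
         exclusionMask = vol(geo$cerebellum), brainMask = vol(geo$brain),
         spec = spec)
}

#' @rdname Cohort-class
#' @param subjects,atlas,exclusionMask,brainMask,spec see slots.
#' @export
Cohort <- function(subjects, atlas, exclusionMask, brainMask, spec = NULL) {
  new("Cohort", subjects = subjects, atlas = atlas,
      exclusionMask = exclusionMask, brainMask = brainMask, spec = spec)
}

#' True regional lesion loads of a cohort
#'
#' Lesion voxel count per atlas region times the voxel volume, from the
#' subjects' ground-truth masks.
#'
#' @param cohort a \linkS4class{Cohort} whose subjects carry true masks.
#' @return subjects x regions matrix of loads in mm^3.
#' @export
regionLesionLoads <- function(cohort) {
  lab <- volData(atlasLabels(cohortAtlas(cohort)))
  nreg <- length(regionNames(cohortAtlas(cohort)))
  voxVol <- voxelVolume(atlasLabels(cohortAtlas(cohort)))
  subs <- cohortSubjects(cohort)
  out <- t(vapply(subs, function(s) {
    m <- volData(trueLesionMask(s)) == 1
    tabulate(lab[m], nbins = nreg) * voxVol
  }, numeric(nreg)))
  rownames(out) <- vapply(subs, subjectId, character(1))
  colnames(out) <- unname(regionNames(cohortAtlas(cohort)))
  out
}

#' Per-subject true lesion volumes (ml)
#'
#' @param cohort a \linkS4class{Cohort}.
#' @return named numeric vector, ml.
#' @export
trueLesionVolumesMl <- function(cohort) {
  subs <- cohortSubjects(cohort)
  v <- vapply(subs, function(s) {
    m <- trueLesionMask(s)
    sum(volData(m)) * voxelVolume(m) / 1000
  }, numeric(1))
  names(v) <- vapply(subs, subjectId, character(1))
  v
}

#' Summarise a cohort
#'
#' One row per demographic variable and per test: mean, SD, min, max, and
#' for tests the partial correlation (controlling sex and education) with
#' age and with true lesion volume, with two-sided p-values. With a single
#' subject SDs and correlations are NA.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @return data.frame.
#' @export
cohortSummary <- function(cohort) {
  subs <- cohortSubjects(cohort)
  n <- length(subs)
  age <- vapply(subs, function(s) covariates(s)$age, numeric(1))
  edu <- vapply(subs, function(s) covariates(s)$education, numeric(1))
  sexF <- as.numeric(vapply(subs, function(s) covariates(s)$sex,
                            character(1)) == "F")
  vml <- unname(trueLesionVolumesMl(cohort))
  tests <- names(scores(subs[[1L]]))
  smat <- vapply(subs, function(s) scores(s)[tests], numeric(length(tests)))
  smat <- matrix(smat, nrow = length(tests),
                 dimnames = list(tests, NULL))
  covmat <- cbind(sex = sexF, education = edu)
  rowFor <- function(name, x, withCorr = TRUE) {
    r_age <- p_age <- r_wml <- p_wml <- NA_real_
    if (withCorr && n > ncol(covmat) + 2 && sd(x) > 0) {
      ca <- try(partialPearson(x, age, covmat), silent = TRUE)
      cw <- try(partialPearson(x, vml, covmat), silent = TRUE)
      if (!inherits(ca, "try-error")) { r_age <- ca$r; p_age <- ca$p }
      if (!inherits(cw, "try-error")) { r_wml <- cw$r; p_wml <- cw$p }
    }
    data.frame(variable = name, mean = mean(x),
               sd = if (n > 1) sd(x) else NA_real_,
               min = min(x), max = max(x),
               r_age = r_age, p_age = p_age,
               r_wml = r_wml, p_wml = p_wml, stringsAsFactors = FALSE)
  }
  out <- rbind(rowFor("age", age, withCorr = FALSE),
               rowFor("education", edu, withCorr = FALSE),
               rowFor("lesion_volume_ml", vml, withCorr = FALSE))
  lv <- try(partialPearson(vml, age, covmat), silent = TRUE)
  if (n > ncol(covmat) + 2 && !inherits(lv, "try-error")) {
    out$r_age[out$variable == "lesion_volume_ml"] <- lv$r
    out$p_age[out$variable == "lesion_volume_ml"] <- lv$p
  }
  for (t in tests) out <- rbind(out, rowFor(t, smat[t, ]))
  rownames(out) <- NULL
  out
}

#' Export a cohort to disk
#'
#' Writes per-subject NIfTI channels and true lesion masks, the atlas and
#' exclusion-mask NIfTIs, a scores TSV, and (when jsonlite is available) a
#' small JSON manifest with grid, regions and seed.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param dir output directory (created if needed).
#' @return invisibly \code{dir}.
#' @export
exportCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeVolume(atlasLabels(cohortAtlas(cohort)), file.path(dir, "atlas.nii.gz"),
              datatype = "int16")
  writeVolume(exclusionMask(cohort), file.path(dir, "exclusion.nii.gz"),
              datatype = "int16")
  writeVolume(brainMask(cohort), file.path(dir, "brain.nii.gz"),
              datatype = "int16")
  for (s in cohortSubjects(cohort)) {
    sd_ <- file.path(dir, subjectId(s))
    dir.create(sd_, showWarnings = FALSE)
    for (ch in names(s@channels))
      writeVolume(channel(s, ch), file.path(sd_, paste0(ch, ".nii.gz")))
    if (!is.null(trueLesionMask(s)))
      writeVolume(trueLesionMask(s), file.path(sd_, "lesion_truth.nii.gz"),
                  datatype = "int16")
  }
  writeScoreTable(cohort, file.path(dir, "scores.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE) && !is.null(cohort@spec)) {
    sp <- cohort@spec
    manifest <- list(gridShape = sp@gridShape, voxelSize = sp@voxelSize,
                     nSubjects = sp@nSubjects, seed = sp@seed,
                     regions = unname(regionNames(cohortAtlas(cohort))))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}
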