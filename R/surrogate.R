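## Deterministic geometric surrogate backend.
##
## Maps a residue string to a StructureModel through hydropathy periodicity:
## an amphipathic helix carries a hydropathy wave of period ~3.6 residues
## (positive autocorrelation at lags 3-4), a strand alternates buried and
## exposed residues (positive autocorrelation at lag 2). Residues are
## labelled H/E/C by the dominant smoothed signal, ideal-geometry
## coordinates are emitted per label (coil is a compact self-avoiding walk
## seeded by a hash of the sequence), per-residue confidence is a logistic
## of local signal strength, and the global confidence a logistic of mean
## confidence and structured fraction. Everything is a pure function of the
## residue string: identical input gives bit-identical output.

## Kyte-Doolittle hydropathy
HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, V = 4.2,
                W = -0.9, Y = -1.3)

## All tunable surrogate constants in one place.
.surrogate_defaults <- list(
  window       = 7,        # sliding window (residues) for signal smoothing
  helixLags    = c(3, 4),  # autocorrelation lags carrying the helix signal
  strandLag    = 2,        # lag carrying the strand signal
  threshold    = 2.2,      # signal level separating structure from coil
  minHelixRun  = 4,        # shortest run kept as helix
  minStrandRun = 3,        # shortest run kept as strand
  plddtMid     = 2.1,      # logistic midpoint for per-residue confidence
  plddtScale   = 0.55,     # logistic steepness for per-residue confidence
  ptmPlddtCoef = 6,        # ptm logistic: weight of (mean plddt - 0.45)
  ptmSsCoef    = 2,        # ptm logistic: weight of (H/E fraction - 0.25)
  helixRise    = 1.5,      # helix rise per residue (Angstrom)
  helixRadius  = 2.3,      # helix CA radius (Angstrom)
  helixTurn    = 100,      # helix turn per residue (degrees)
  strandRise   = 3.3,      # strand rise per residue (Angstrom)
  strandWobble = 0.8,      # strand pleat amplitude (Angstrom)
  coilStep     = 3.8,      # CA-CA virtual bond length (Angstrom)
  coilBias     = 0.35,     # pull of the coil walk toward the centroid
  clashDist    = 3.0)      # CA-CA distance treated as a clash

#' The deterministic surrogate structure backend
#'
#' Builds a [SurrogateEvaluator], a desk-scale deterministic stand-in for a
#' neural structure predictor. It is honest about what it is: a fixture
#' whose structures are geometrically plausible but not physically
#' realistic, designed so that every downstream stage (scoring, selection,
#' lineage analysis) can run and be tested without a GPU predictor.
#'
#' @param ... named overrides of the surrogate constants (see
#'   `foldevo:::.surrogate_defaults` for the full list).
#' @return a [SurrogateEvaluator].
#' @examples
#' ev <- surrogateEvaluator()
#' m <- evaluateStructure(ev, "LKKLEEKLKKLEEKLKKLEEKLKKLEEK")[[1]]
#' mean(plddt(m))
#' @export
surrogateEvaluator <- function(...) {
  params <- utils::modifyList(.surrogate_defaults, list(...))
  new("SurrogateEvaluator", deterministic = TRUE, batchCapable = TRUE,
      params = params)
}

## trailing fixed-denominator running mean with zero padding. Two
## properties matter: (a) windows truncated at the N-terminus keep the
## full-window denominator, so signal ramps up over the first `width`
## residues (terminal residues of an element are less certain than interior
## ones); (b) the window is trailing and exactly `width` long, so for a
## hydropathy wave whose repeat equals `width` the steady-state signal is
## exactly phase-independent -- growing a periodic element can only add
## residues at or above the head-ramp values, never below, which makes mean
## confidence non-decreasing in element length.
.runmean_trailing <- function(x, width) {
  L <- length(x)
  x[is.na(x)] <- 0
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(L) - width + 1L, 1L)
  (cs[seq_len(L) + 1L] - cs[lo]) / width
}

## partial-window running mean, NA entries ignored
.runmean_partial <- function(x, half) {
  L <- length(x)
  ok <- !is.na(x)
  xs <- ifelse(ok, x, 0)
  cs <- c(0, cumsum(xs))
  cn <- c(0, cumsum(ok))
  lo <- pmax(seq_len(L) - half, 1L)
  hi <- pmin(seq_len(L) + half, L)
  s <- cs[hi + 1L] - cs[lo]
  nct <- cn[hi + 1L] - cn[lo]
  ifelse(nct > 0, s / nct, 0)
}

## lag-k hydropathy product series, attributed to the right endpoint of the
## pair (causal: a residue's signal depends only on itself and what precedes
## it, so extending a chain never changes existing per-residue signals)
.lag_series <- function(hc, k) {
  L <- length(hc)
  z <- rep(NA_real_, L)
  if (L > k) z[(k + 1L):L] <- hc[seq_len(L - k)] * hc[(k + 1L):L]
  z
}

## per-residue helix/strand signals from hydropathy periodicity; the
## hydropathy series is centred by its local running mean, so periodicity
## is detected independently of overall composition and of chain length
.surrogate_signals <- function(res_chars, params) {
  h <- unname(HYDROPATHY[res_chars])
  w <- params$window
  hc <- h - .runmean_trailing(h, w)
  lagsum <- .runmean_trailing(.lag_series(hc, params$helixLags[1]), w)
  for (k in params$helixLags[-1])
    lagsum <- lagsum + .runmean_trailing(.lag_series(hc, k), w)
  esig <- .runmean_trailing(.lag_series(hc, params$strandLag), w)
  list(helix = lagsum / length(params$helixLags), strand = esig)
}

## H/E/C labels from the dominant signal, short runs demoted to coil
.surrogate_labels <- function(sig, params) {
  L <- length(sig$helix)
  lab <- rep("C", L)
  lab[sig$helix > params$threshold & sig$helix >= sig$strand] <- "H"
  lab[sig$strand > params$threshold & sig$strand > sig$helix] <- "E"
  r <- rle(lab)
  drop <- (r$values == "H" & r$lengths < params$minHelixRun) |
          (r$values == "E" & r$lengths < params$minStrandRun)
  r$values[drop] <- "C"
  inverse.rle(r)
}

## deterministic per-sequence uniform draws for the coil walk: a hash of
## the residue string seeds a private RNG whose state is saved/restored, so
## the surrogate is a pure function of the sequence and leaves the caller's
## RNG untouched
.seq_uniforms <- function(res_chars, n) {
  seed <- sum(utf8ToInt(paste(res_chars, collapse = "")) *
              (seq_along(res_chars) %% 97 + 1)) %% 2147483587
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  stats::runif(n)
}

.unit <- function(v) {
  nv <- sqrt(sum(v * v))
  if (nv < 1e-12) c(1, 0, 0) else v / nv
}

## any unit vector perpendicular to d
.perp <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  .unit(ref - sum(ref * d) * d)
}

## CA trace: ideal helix/strand geometry per labelled segment, compact
## self-avoiding random walk (sequence-hashed draws) for coil
.build_ca_trace <- function(labels, draws, params) {
  L <- length(labels)
  ca <- matrix(0, L, 3)
  pos <- c(0, 0, 0)
  dir <- c(1, 0, 0)
  ptr <- 0L
  csum <- c(0, 0, 0)          # running sum of placed CAs (for the centroid)
  clash2 <- params$clashDist^2
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  placed <- 0L
  for (s in seq_along(r$values)) {
    idx <- starts[s]:ends[s]
    m <- length(idx)
    if (r$values[s] == "H") {
      a <- .perp(dir); b <- .unit(.cross(dir, a))
      th <- seq_len(m) * params$helixTurn * pi / 180
      t <- seq_len(m) * params$helixRise
      rad <- params$helixRadius
      seg <- cbind(pos[1] + t * dir[1] + rad * (cos(th) * a[1] + sin(th) * b[1]),
                   pos[2] + t * dir[2] + rad * (cos(th) * a[2] + sin(th) * b[2]),
                   pos[3] + t * dir[3] + rad * (cos(th) * a[3] + sin(th) * b[3]))
      ca[idx, ] <- seg
      pos <- seg[m, ]
    } else if (r$values[s] == "E") {
      u <- .perp(dir)
      t <- seq_len(m) * params$strandRise
      wob <- params$strandWobble * (-1)^(seq_len(m))
      seg <- cbind(pos[1] + t * dir[1] + wob * u[1],
                   pos[2] + t * dir[2] + wob * u[2],
                   pos[3] + t * dir[3] + wob * u[3])
      ca[idx, ] <- seg
      pos <- seg[m, ]
    } else {
      step <- params$coilStep
      cbias <- params$coilBias
      px <- pos[1]; py <- pos[2]; pz <- pos[3]
      dx <- dir[1]; dy <- dir[2]; dz <- dir[3]
      for (i in idx) {
        if (placed > 1L) {
          cx <- csum[1] / placed - px; cy <- csum[2] / placed - py
          cz <- csum[3] / placed - pz
          cn <- sqrt(cx * cx + cy * cy + cz * cz)
          if (cn > 1e-12) { cx <- cx / cn; cy <- cy / cn; cz <- cz / cn }
        } else cx <- cy <- cz <- 0
        bx <- 0.55 * dx + cbias * cx; by <- 0.55 * dy + cbias * cy
        bz <- 0.55 * dz + cbias * cz
        for (try in 1:8) {
          gx <- draws[ptr + 1L] - 0.5; gy <- draws[ptr + 2L] - 0.5
          gz <- draws[ptr + 3L] - 0.5
          ptr <- ptr + 3L
          gn <- sqrt(gx * gx + gy * gy + gz * gz)
          if (gn < 1e-12) { gx <- 1; gn <- 1 }
          nx <- bx + 0.65 * gx / gn; ny <- by + 0.65 * gy / gn
          nz <- bz + 0.65 * gz / gn
          nn <- sqrt(nx * nx + ny * ny + nz * nz)
          nx <- nx / nn; ny <- ny / nn; nz <- nz / nn
          qx <- px + step * nx; qy <- py + step * ny; qz <- pz + step * nz
          if (placed == 0L) break
          pl <- seq_len(placed)
          if (min((ca[pl, 1] - qx)^2 + (ca[pl, 2] - qy)^2 +
                  (ca[pl, 3] - qz)^2) >= clash2) break
        }
        ca[i, 1] <- qx; ca[i, 2] <- qy; ca[i, 3] <- qz
        csum[1] <- csum[1] + qx; csum[2] <- csum[2] + qy
        csum[3] <- csum[3] + qz
        px <- qx; py <- qy; pz <- qz
        dx <- nx; dy <- ny; dz <- nz
        placed <- i
      }
      pos <- c(px, py, pz)
      dir <- c(dx, dy, dz)
      next
    }
    csum <- csum + colSums(ca[idx, , drop = FALSE])
    placed <- ends[s]
  }
  ca
}

.cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

## N, C, CB from the CA trace; glycine CB = CA
.backbone_from_ca <- function(ca, res_chars) {
  L <- nrow(ca)
  if (L == 1L) {
    tprev <- matrix(c(1, 0, 0), 1L, 3L)
    tnext <- tprev
  } else {
    d <- diff(ca)                      # (L-1) x 3
    dn <- d / pmax(sqrt(rowSums(d^2)), 1e-12)
    tprev <- rbind(dn[1, , drop = FALSE], dn)   # direction arriving at i
    tnext <- rbind(dn, dn[L - 1L, , drop = FALSE]) # direction leaving i
  }
  nmat <- ca - 1.46 * tprev
  cmat <- ca + 1.52 * tnext
  bis <- -(tprev + tnext) / 2
  bn <- sqrt(rowSums(bis^2))
  flat <- bn < 0.1
  if (any(flat)) {
    for (i in which(flat)) bis[i, ] <- .perp(tnext[i, ])
    bn[flat] <- 1
  }
  cb <- ca + 1.53 * bis / bn
  gly <- res_chars == "G"
  cb[gly, ] <- ca[gly, , drop = FALSE]
  list(n = nmat, ca = ca, c = cmat, cb = cb)
}

## the full deterministic surrogate: residue string -> StructureModel
.surrogate_model <- function(res, params) {
  res_chars <- strsplit(res, "")[[1]]
  L <- length(res_chars)
  sig <- .surrogate_signals(res_chars, params)
  labels <- .surrogate_labels(sig, params)
  draws <- .seq_uniforms(res_chars, 24L * L + 24L)
  ca <- .build_ca_trace(labels, draws, params)
  bb <- .backbone_from_ca(ca, res_chars)
  strength <- pmax(sig$helix, sig$strand, 0)
  smooth <- .runmean_trailing(strength, params$window)
  pl <- 1 / (1 + exp(-params$plddtScale * (smooth - params$plddtMid)))
  frac_ss <- mean(labels != "C")
  ptm <- 1 / (1 + exp(-(params$ptmPlddtCoef * (mean(pl) - 0.45) +
                        params$ptmSsCoef * (frac_ss - 0.25))))
  new("StructureModel", residues = res_chars, chain = rep("A", L),
      n = bb$n, ca = bb$ca, c = bb$c, cb = bb$cb,
      plddt = pl, ptm = ptm)
}

## deterministic rigid placement of the evolving chain against the fixed
## partner: both centred, evolving chain shifted along +x until the chains
## just touch (4.5 A gap between closest CB x-extents)
.surrogate_dimer <- function(evolving, partner) {
  shift_chain <- function(co, delta) sweep(co, 2, delta, "+")
  pcen <- colMeans(partner@ca)
  ecen <- colMeans(evolving@ca)
  pshift <- -pcen
  px <- max(partner@cb[, 1] + pshift[1])
  eshift0 <- -ecen
  ex <- min(evolving@cb[, 1] + eshift0[1])
  eshift <- eshift0 + c(px - ex + 4.5, 0, 0)
  comb <- function(at) rbind(shift_chain(slot(evolving, at), eshift),
                             shift_chain(slot(partner, at), pshift))
  new("StructureModel",
      residues = c(evolving@residues, partner@residues),
      chain = c(rep("A", length(evolving@residues)),
                rep("B", length(partner@residues))),
      n = comb("n"), ca = comb("ca"), c = comb("c"), cb = comb("cb"),
      plddt = c(evolving@plddt, partner@plddt),
      ptm = evolving@ptm)
}

#' @rdname evaluateStructure
#' @export
setMethod("evaluateStructure", "SurrogateEvaluator",
  function(evaluator, sequences, partner = NULL) {
    seqs <- if (is.list(sequences)) vapply(sequences, residues, character(1))
            else sequences
    if (!is.null(partner)) {
      if (length(chains(partner)) != 1L)
        stop("the fixed partner must be a single chain")
      lapply(seqs, function(s)
        .surrogate_dimer(.surrogate_model(s, evaluator@params), partner))
    } else {
      lapply(seqs, function(s) .surrogate_model(s, evaluator@params))
    }
  })
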