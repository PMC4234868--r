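# Independent scalar reference tracer. Re-implements the photon transport in
# plain R, consuming the same rand48 stream as the compiled kernel, so the
# two can be compared packet by packet on a shared random sequence.

# 48-bit LCG (rand48 constants) in exact 24-bit limb arithmetic
lcg48New <- function(seed) {
  state <- seed * 65536 + 13070
  lo <- state %% 16777216
  env <- new.env(parent = emptyenv())
  env$lo <- lo
  env$hi <- ((state - lo) / 16777216) %% 16777216
  env
}

lcg48Next <- function(r) {
  a <- 25214903917
  a1 <- a %% 16777216          # low 24 bits of the multiplier
  a2 <- (a - a1) / 16777216    # high bits
  lo <- a1 * r$lo + 11
  nlo <- lo %% 16777216
  carry <- (lo - nlo) / 16777216
  nhi <- (a1 * r$hi + a2 * r$lo + carry) %% 16777216
  r$lo <- nlo
  r$hi <- nhi
  (nhi * 16777216 + nlo + 1) / 281474976710656
}

# Henyey-Greenstein direction update, mirroring the kernel expression by
# expression
oracleScatter <- function(g, u1, u2, ux, uy, uz) {
  if (g == 0) {
    ct <- 2 * u1 - 1
  } else {
    tmp <- (1 - g * g) / (1 - g + 2 * g * u1)
    ct <- (1 + g * g - tmp * tmp) / (2 * g)
  }
  if (ct > 1) ct <- 1
  if (ct < -1) ct <- -1
  st <- sqrt(1 - ct * ct)
  phi <- 2 * pi * u2
  cp <- cos(phi)
  sp <- sin(phi)
  if (abs(uz) > 0.99999) {
    c(st * cp, st * sp, if (uz >= 0) ct else -ct)
  } else {
    den <- sqrt(1 - uz * uz)
    c(st * (ux * uz * cp - uy * sp) / den + ux * ct,
      st * (uy * uz * cp + ux * sp) / den + uy * ct,
      -den * st * cp + uz * ct)
  }
}

# Scalar tracer: layered slab, absorbing outer boundaries, absorbing probe
# tip plane at z0 with a collecting detector disc. Units: cm.
oracleTrace <- function(model, probe, probeDepthMm, seed, nPhotons,
                        wmin = 1e-4, psurv = 0.1) {
  muAv <- vapply(model@layers, function(p) muA(p), numeric(1))
  muSv <- vapply(model@layers, function(p) muS(p), numeric(1))
  gv <- vapply(model@layers, function(p) anisotropy(p), numeric(1))
  zb <- c(0, cumsum(layerThickness(model) / 10))
  L <- length(muAv)
  mt <- muAv + muSv
  invMt <- 1 / mt
  absFrac <- muAv / mt
  z0 <- probeDepthMm / 10
  detx <- probe@separationUm * 1e-4
  detr2 <- (probe@fiberDiameterUm / 2 * 1e-4)^2
  cosMin <- probe@acceptanceCosMin
  rng <- lcg48New(seed)
  out <- matrix(0, nPhotons, 4,
                dimnames = list(NULL, c("detected", "escaped", "absorbed",
                                        "roulette")))
  for (ph in seq_len(nPhotons)) {
    x <- 0; y <- 0; z <- z0
    ux <- 0; uy <- 0; uz <- 1
    w <- 1
    cur <- 1
    while (cur < L && z0 >= zb[cur + 1]) cur <- cur + 1
    det <- 0; esc <- 0; absb <- 0; roul <- 0
    alive <- TRUE
    while (alive) {
      srem <- -log(lcg48Next(rng))
      interact <- FALSE
      repeat {
        mut <- mt[cur]
        d <- srem * invMt[cur]
        znew <- z + d * uz
        if (uz > 0) {
          if (znew < zb[cur + 1]) {
            x <- x + d * ux; y <- y + d * uy; z <- znew
            interact <- TRUE
            break
          }
          tb <- (zb[cur + 1] - z) / uz
          x <- x + tb * ux; y <- y + tb * uy
          srem <- srem - tb * mut
          z <- zb[cur + 1]
          if (cur == L) { esc <- w; alive <- FALSE; break }
          cur <- cur + 1
          next
        }
        if (uz < 0) {
          zlim <- if (z0 >= zb[cur]) z0 else zb[cur]
          if (znew > zlim) {
            x <- x + d * ux; y <- y + d * uy; z <- znew
            interact <- TRUE
            break
          }
          tb <- (zlim - z) / uz
          x <- x + tb * ux; y <- y + tb * uy
          srem <- srem - tb * mut
          z <- zlim
          if (zlim == z0) {
            dx <- x - detx
            r2 <- dx * dx + y * y
            if (r2 <= detr2 && -uz >= cosMin) det <- w else esc <- w
            alive <- FALSE
            break
          }
          if (cur == 1) { esc <- w; alive <- FALSE; break }
          cur <- cur - 1
          next
        }
        x <- x + d * ux; y <- y + d * uy
        interact <- TRUE
        break
      }
      if (!alive || !interact) next
      aw <- w * absFrac[cur]
      absb <- absb + aw
      w <- w - aw
      if (w < wmin) {
        u <- lcg48Next(rng)
        if (u <= psurv) {
          roul <- roul - w * 9
          w <- w * 10
        } else {
          roul <- roul + w
          alive <- FALSE
          next
        }
      }
      u1 <- lcg48Next(rng)
      u2 <- lcg48Next(rng)
      dir <- oracleScatter(gv[cur], u1, u2, ux, uy, uz)
      ux <- dir[1]; uy <- dir[2]; uz <- dir[3]
    }
    out[ph, ] <- c(det, esc, absb, roul)
  }
  out
}
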