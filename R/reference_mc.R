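# Independently coded reference transport simulation, used to validate the
# compiled engine.  Same physics (weighted hop-drop-spin, Henyey-Greenstein
# scattering, probabilistic Fresnel boundaries, ledger-exact roulette), but a
# separate implementation: plain R, array-at-a-time over photons, driven by
# R's own RNG rather than the engine's generator.  Agreement is therefore a
# statistical check (shared seeds are meaningless across the two engines).

#' Reference Monte Carlo simulation (validation oracle)
#'
#' A straightforward R implementation of the layered-slab transport physics,
#' written independently of the compiled engine so the two can be compared
#' as a cross-check.  It is orders of magnitude slower and intended only for
#' validation at modest photon counts.
#'
#' @inheritParams simulate_rt
#' @return An object of class `rt_result` (same fields as [simulate_rt()]).
#' @seealso [simulate_rt()]
#' @export
simulate_rt_reference <- function(stack, beam = beam_geometry(),
                                  detector = detector_geometry(),
                                  n_photons = 1e4, seed = 1,
                                  w_threshold = 1e-4, roulette_p = 0.1) {
  stopifnot(inherits(stack, "layer_stack"), n_photons >= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  Ldf <- stack$layers
  nl <- nrow(Ldf)
  amb <- stack$ambient_n
  mut <- Ldf$mu_a + Ldf$mu_s
  zbot <- cumsum(Ldf$thickness)
  ztop <- c(0, zbot[-nl])
  cone_cos <- cos(detector$specular_cone_deg * pi / 180)
  maxr2 <- detector$sample_halfwidth^2
  port2 <- detector$port_radius^2

  # collimated reflectance of a pile of lossless interfaces at normal
  # incidence, built by forward composition:
  #   R <- R + T^2 r / (1 - R r);  T <- T t / (1 - R r)
  pile_reflectance <- function(ns) {
    R <- 0; Tc <- 1
    for (k in seq_len(length(ns) - 1)) {
      r <- fresnel_reflectance(ns[k], ns[k + 1], 1)
      denom <- 1 - R * r
      Rnew <- R + Tc^2 * r / denom
      Tc <- Tc * (1 - r) / denom
      R <- Rnew
    }
    R
  }

  k0 <- which(mut > 0)[1]
  if (is.na(k0)) {
    Rtot <- pile_reflectance(c(amb, Ldf$n, amb))
    out <- list(specular = Rtot, Rd = 0, Tt = 1 - Rtot, absorbed = 0,
                lost = 0, se_Rd = 0, se_Tt = 0, n_photons = n_photons,
                seed = seed)
    class(out) <- "rt_result"
    return(out)
  }
  R_spec <- pile_reflectance(c(amb, Ldf$n[seq_len(k0)]))

  N <- as.integer(n_photons)
  br <- beam$diameter / 2
  if (br > 0) {
    rr <- br * sqrt(stats::runif(N))
    ph <- 2 * pi * stats::runif(N)
    x <- rr * cos(ph); y <- rr * sin(ph)
  } else {
    x <- numeric(N); y <- numeric(N)
  }
  z <- rep(ztop[k0], N)
  ux <- numeric(N); uy <- numeric(N); uz <- rep(1, N)
  w <- rep(1 - R_spec, N)
  lay <- rep(k0, N)
  s <- numeric(N)
  alive <- rep(TRUE, N)

  contribRd <- numeric(N); contribTt <- numeric(N)
  t_spec_diff <- 0; t_abs <- 0; t_lost <- 0

  iter <- 0
  while (any(alive)) {
    iter <- iter + 1
    if (iter > 2e6) { t_lost <- t_lost + sum(w[alive]); break }
    ia <- which(alive)
    need <- ia[s[ia] <= 0]
    if (length(need)) s[need] <- -log(stats::runif(length(need)))

    mt <- mut[lay[ia]]
    uzv <- uz[ia]
    db <- rep(Inf, length(ia))
    dn <- uzv > 0; up <- uzv < 0
    db[dn] <- (zbot[lay[ia][dn]] - z[ia][dn]) / uzv[dn]
    db[up] <- (ztop[lay[ia][up]] - z[ia][up]) / uzv[up]

    stuck <- mt <= 0 & !is.finite(db)          # horizontal in glass
    bnd <- (mt <= 0 & is.finite(db)) | (mt > 0 & db * mt <= s[ia])
    step <- ifelse(bnd, db, s[ia] / pmax(mt, .Machine$double.xmin))
    step[stuck] <- 0

    x[ia] <- x[ia] + ux[ia] * step
    y[ia] <- y[ia] + uy[ia] * step
    z[ia] <- z[ia] + uz[ia] * step
    s[ia] <- ifelse(bnd, s[ia] - ifelse(mt > 0, db * mt, 0), 0)

    if (any(stuck)) {
      ids <- ia[stuck]
      t_lost <- t_lost + sum(w[ids]); alive[ids] <- FALSE
    }
    out_r <- x[ia]^2 + y[ia]^2 > maxr2 & alive[ia]
    if (any(out_r)) {
      ids <- ia[out_r]
      t_lost <- t_lost + sum(w[ids]); alive[ids] <- FALSE
    }

    ib <- ia[bnd & alive[ia]]
    if (length(ib)) {
      godown <- uz[ib] > 0
      nxt <- lay[ib] + ifelse(godown, 1L, -1L)
      inside <- nxt >= 1 & nxt <= nl
      ni <- Ldf$n[lay[ib]]
      nt <- ifelse(inside, Ldf$n[pmax(pmin(nxt, nl), 1)], amb)
      cosi <- abs(uz[ib])
      Rf <- fresnel_reflectance(ni, nt, cosi)
      refl <- stats::runif(length(ib)) < Rf

      ir <- ib[refl]
      if (length(ir)) {
        uz[ir] <- -uz[ir]
        z[ir] <- ifelse(godown[refl], zbot[lay[ir]], ztop[lay[ir]])
      }
      it <- ib[!refl]
      if (length(it)) {
        gd <- godown[!refl]; ins <- inside[!refl]
        ratio <- (ni / nt)[!refl]
        cost <- sqrt(pmax(0, 1 - ratio^2 * (1 - cosi[!refl]^2)))
        ux[it] <- ux[it] * ratio
        uy[it] <- uy[it] * ratio
        uz[it] <- ifelse(gd, cost, -cost)
        # crossing into another layer
        iin <- it[ins]
        if (length(iin)) {
          lay[iin] <- nxt[!refl][ins]
          z[iin] <- ifelse(gd[ins], ztop[lay[iin]], zbot[lay[iin]])
        }
        # exiting the stack
        iex <- it[!ins]
        if (length(iex)) {
          gdx <- gd[!ins]; cx <- cost[!ins]
          r2 <- x[iex]^2 + y[iex]^2
          top <- !gdx
          sp <- top & cx >= cone_cos
          rd <- top & !sp & r2 <= port2
          tl <- top & !sp & !rd
          tt <- gdx & r2 <= port2
          bl <- gdx & !tt
          t_spec_diff <- t_spec_diff + sum(w[iex][sp])
          contribRd[iex[rd]] <- w[iex[rd]]
          contribTt[iex[tt]] <- w[iex[tt]]
          t_lost <- t_lost + sum(w[iex][tl | bl])
          alive[iex] <- FALSE
        }
      }
    }

    ii <- ia[!bnd & !stuck & alive[ia]]
    if (length(ii)) {
      mti <- mut[lay[ii]]
      dw <- w[ii] * Ldf$mu_a[lay[ii]] / mti
      t_abs <- t_abs + sum(dw)
      w[ii] <- w[ii] - dw
      gone <- w[ii] <= 0
      if (any(gone)) alive[ii[gone]] <- FALSE
      ii <- ii[!gone]
      if (length(ii)) {
        gv <- Ldf$g[lay[ii]]
        u1 <- stats::runif(length(ii))
        f <- (1 - gv^2) / (1 - gv + 2 * gv * u1)
        ct <- ifelse(gv == 0, 2 * u1 - 1,
                     pmin(1, pmax(-1, (1 + gv^2 - f^2) / (2 * gv))))
        st <- sqrt(pmax(0, 1 - ct^2))
        phi <- 2 * pi * stats::runif(length(ii))
        cp <- cos(phi); sp2 <- sin(phi)
        near <- abs(uz[ii]) > 0.99999
        den <- sqrt(pmax(1e-24, 1 - uz[ii]^2))
        nux <- st * (ux[ii] * uz[ii] * cp - uy[ii] * sp2) / den + ux[ii] * ct
        nuy <- st * (uy[ii] * uz[ii] * cp + ux[ii] * sp2) / den + uy[ii] * ct
        nuz <- -den * st * cp + uz[ii] * ct
        nux[near] <- (st * cp)[near]
        nuy[near] <- (st * sp2)[near]
        nuz[near] <- (sign(uz[ii]) * ct)[near]
        ux[ii] <- nux; uy[ii] <- nuy; uz[ii] <- nuz

        low <- w[ii] < w_threshold
        if (any(low)) {
          il <- ii[low]
          surv <- stats::runif(length(il)) < roulette_p
          is_ <- il[surv]
          if (length(is_)) {
            t_abs <- t_abs - sum(w[is_]) * (1 / roulette_p - 1)
            w[is_] <- w[is_] / roulette_p
          }
          ik <- il[!surv]
          if (length(ik)) {
            t_abs <- t_abs + sum(w[ik])
            alive[ik] <- FALSE
          }
        }
      }
    }
  }

  Rd <- sum(contribRd) / N
  Tt <- sum(contribTt) / N
  se <- function(v) if (N > 1) stats::sd(v) / sqrt(N) else 0
  out <- list(specular = R_spec + t_spec_diff / N, Rd = Rd, Tt = Tt,
              absorbed = t_abs / N, lost = t_lost / N,
              se_Rd = se(contribRd), se_Tt = se(contribTt),
              n_photons = N, seed = seed)
  class(out) <- "rt_result"
  out
}
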