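# Independent, deliberately naive re-implementations used as oracles.
# All are plain loops over base-R structures so they share no code path
# with the package's vectorised implementations.

# --- consensus filter: literal per-variant rule evaluation ----------------
oracle_filter_matched <- function(a, b, repeats = NULL, popfreq_cut = 0.01,
                                  solo_vaf = 0.05) {
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, v$class)
  ka <- key(a)
  kb <- key(b)
  keys <- union(ka, kb)
  kept <- character(0)
  for (k in keys) {
    ia <- match(k, ka)
    ib <- match(k, kb)
    in_a <- !is.na(ia)
    in_b <- !is.na(ib)
    g <- function(field) {
      vb <- if (in_b) b[[field]][ib] else NA
      va <- if (in_a) a[[field]][ia] else NA
      if (!is.na(vb)) vb else va
    }
    cls <- g("class")
    p_cut <- if (identical(cls, "INDEL")) 0.05 else 0.1
    nar_cut <- if (identical(cls, "INDEL")) 2 else 5
    sp <- g("somatic_p")
    tv <- g("tumor_vaf")
    consensus <- in_a && in_b && !is.na(sp) && sp <= p_cut &&
      !is.na(tv) && tv > 0.02
    solo_b <- !in_a && in_b && !is.na(tv) && tv > solo_vaf
    nv <- g("normal_vaf")
    nr <- g("normal_alt_reads")
    normal_ok <- (is.na(nv) || nv < 0.01) && (is.na(nr) || nr < nar_cut)
    afs <- c(g("af_1kg"), g("af_exac"), g("af_esp"))
    afs[is.na(afs)] <- 0
    pop_ok <- min(afs) < popfreq_cut
    pos <- g("pos")
    chrom <- g("chrom")
    in_rep <- FALSE
    if (!is.null(repeats)) {
      for (j in seq_len(nrow(repeats))) {
        if (repeats$chrom[j] == chrom && pos >= repeats$start[j] &&
            pos <= repeats$end[j]) {
          in_rep <- TRUE
          break
        }
      }
    }
    if ((consensus || solo_b) && normal_ok && pop_ok && !in_rep) {
      kept <- c(kept, k)
    }
  }
  sort(kept)
}

# --- interval helpers -----------------------------------------------------
clip_to_arm <- function(s, e, arm_s, arm_e) {
  cs <- max(s, arm_s)
  ce <- min(e, arm_e)
  if (cs > ce) NULL else c(cs, ce)
}

# --- HRD-LOH: merge-and-count with centromere bridging --------------------
oracle_hrd_loh_one <- function(segs, arms, min_bp = 15e6, tol = 1) {
  count <- 0
  for (ch in unique(arms$chrom)) {
    a <- arms[arms$chrom == ch, ]
    chrom_arm_bp <- sum(a$end - a$start + 1)
    cen <- c(a$cen_start[1], a$cen_end[1])
    pieces <- list()
    s_ch <- segs[segs$chrom == ch & segs$n_minor == 0 & segs$n_total >= 1, ]
    if (nrow(s_ch) > 0) {
      for (i in seq_len(nrow(s_ch))) {
        for (j in seq_len(nrow(a))) {
          cl <- clip_to_arm(s_ch$start[i], s_ch$end[i], a$start[j], a$end[j])
          if (!is.null(cl)) pieces[[length(pieces) + 1]] <- cl
        }
      }
    }
    if (length(pieces) == 0) next
    m <- do.call(rbind, pieces)
    m <- m[order(m[, 1]), , drop = FALSE]
    regions <- list()
    cur <- m[1, ]
    cur_bp <- cur[2] - cur[1] + 1
    if (nrow(m) > 1) {
      for (i in 2:nrow(m)) {
        gap <- m[i, 1] - cur[2] - 1
        bridges <- cur[2] >= cen[1] - 1 - tol && m[i, 1] <= cen[2] + 1 + tol
        if (gap <= tol || bridges) {
          cur[2] <- max(cur[2], m[i, 2])
          cur_bp <- cur_bp + (m[i, 2] - m[i, 1] + 1)
        } else {
          regions[[length(regions) + 1]] <- cur_bp
          cur <- m[i, ]
          cur_bp <- cur[2] - cur[1] + 1
        }
      }
    }
    regions[[length(regions) + 1]] <- cur_bp
    for (bp in regions) {
      if (bp > min_bp && bp < chrom_arm_bp - tol) count <- count + 1
    }
  }
  count
}

# --- TAI: telomere-touching allelic-imbalance regions per arm -------------
oracle_tai_one <- function(segs, arms, min_bp = 1e6, telomere_tol = 1000) {
  count <- 0
  ai <- segs[2 * segs$n_minor != segs$n_total, , drop = FALSE]
  for (j in seq_len(nrow(arms))) {
    a <- arms[j, ]
    pieces <- list()
    s_ch <- ai[ai$chrom == a$chrom, , drop = FALSE]
    for (i in seq_len(nrow(s_ch))) {
      cl <- clip_to_arm(s_ch$start[i], s_ch$end[i], a$start, a$end)
      if (!is.null(cl)) pieces[[length(pieces) + 1]] <- cl
    }
    if (length(pieces) == 0) next
    m <- do.call(rbind, pieces)
    m <- m[order(m[, 1]), , drop = FALSE]
    regions <- list(m[1, ])
    if (nrow(m) > 1) {
      for (i in 2:nrow(m)) {
        cur <- regions[[length(regions)]]
        if (m[i, 1] - cur[2] - 1 <= 1) {
          regions[[length(regions)]] <- c(cur[1], max(cur[2], m[i, 2]))
        } else {
          regions[[length(regions) + 1]] <- m[i, ]
        }
      }
    }
    for (r in regions) {
      long_enough <- (r[2] - r[1] + 1) > min_bp
      touches <- if (a$arm == "p") {
        r[1] <= a$start + telomere_tol
      } else {
        r[2] >= a$end - telomere_tol
      }
      if (long_enough && touches) count <- count + 1
    }
  }
  count
}

# --- LST: pairwise scan after smoothing per arm ---------------------------
oracle_lst_one <- function(segs, arms, min_flank_bp = 10e6,
                           max_gap_bp = 3e6, smooth_bp = 3e6) {
  count <- 0
  for (j in seq_len(nrow(arms))) {
    a <- arms[j, ]
    s_ch <- segs[segs$chrom == a$chrom, , drop = FALSE]
    pieces <- list()
    for (i in seq_len(nrow(s_ch))) {
      cl <- clip_to_arm(s_ch$start[i], s_ch$end[i], a$start, a$end)
      if (!is.null(cl) && (cl[2] - cl[1] + 1) >= smooth_bp) {
        pieces[[length(pieces) + 1]] <-
          c(cl, s_ch$n_total[i], s_ch$n_minor[i])
      }
    }
    if (length(pieces) < 2) next
    m <- do.call(rbind, pieces)
    m <- m[order(m[, 1]), , drop = FALSE]
    merged <- list(m[1, ])
    for (i in 2:nrow(m)) {
      cur <- merged[[length(merged)]]
      if (m[i, 3] == cur[3] && m[i, 4] == cur[4]) {
        merged[[length(merged)]] <- c(cur[1], max(cur[2], m[i, 2]),
                                      cur[3], cur[4])
      } else {
        merged[[length(merged) + 1]] <- m[i, ]
      }
    }
    if (length(merged) < 2) next
    for (i in 2:length(merged)) {
      left <- merged[[i - 1]]
      right <- merged[[i]]
      gap <- right[1] - left[2] - 1
      if (gap <= max_gap_bp &&
          (left[2] - left[1] + 1) >= min_flank_bp &&
          (right[2] - right[1] + 1) >= min_flank_bp) {
        count <- count + 1
      }
    }
  }
  count
}

# --- arm events: literal bp accounting ------------------------------------
oracle_arm_events_one <- function(segs, arms, min_fraction = 0.5) {
  cls <- function(nt, nm) {
    if (nt == 2 && nm == 0) "upd"
    else if (nt < 2) "loss"
    else if (nt > 2) "gain"
    else "neutral"
  }
  out <- data.frame(arm_id = arms$arm_id, state = "neutral",
                    fraction = 0, stringsAsFactors = FALSE)
  prio <- c(upd = 1, loss = 2, gain = 3)
  for (j in seq_len(nrow(arms))) {
    a <- arms[j, ]
    bp <- c(upd = 0, loss = 0, gain = 0, neutral = 0)
    s_ch <- segs[segs$chrom == a$chrom, , drop = FALSE]
    for (i in seq_len(nrow(s_ch))) {
      cl <- clip_to_arm(s_ch$start[i], s_ch$end[i], a$start, a$end)
      if (!is.null(cl)) {
        st <- cls(s_ch$n_total[i], s_ch$n_minor[i])
        bp[st] <- bp[st] + (cl[2] - cl[1] + 1)
      }
    }
    frac <- bp / (a$end - a$start + 1)
    cand <- frac[c("upd", "loss", "gain")]
    cand <- cand[cand >= min_fraction]
    if (length(cand) > 0) {
      best <- names(cand)[order(-cand, prio[names(cand)])][1]
      out$state[j] <- best
      out$fraction[j] <- frac[best]
    } else {
      out$fraction[j] <- frac["neutral"]
    }
  }
  out
}

# --- exact Wilcoxon p by full enumeration of rank assignments -------------
oracle_wilcoxon_exact <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  w_all <- apply(sets, 2, function(idx) {
    sum(ranks[idx]) - n1 * (n1 + 1) / 2
  })
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# --- exact two-sided Fisher p by hypergeometric enumeration ---------------
oracle_fisher_exact <- function(a, b, c_, d_) {
  m <- a + c_
  n <- b + d_
  k <- a + b
  x_min <- max(0, k - n)
  x_max <- min(k, m)
  probs <- stats::dhyper(x_min:x_max, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
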