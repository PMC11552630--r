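# Independent brute-force oracles used to validate the fast implementations.
# These deliberately share no code with the package internals.

# exhaustive between-class-variance search over every candidate threshold
brute_otsu <- function(img) {
  px <- as.vector(unclass(img))
  best_t <- NA_integer_
  best_v <- -Inf
  for (t in 0:254) {
    bg <- px[px <= t]
    fg <- px[px > t]
    if (length(bg) == 0L || length(fg) == 0L) next
    v <- length(bg) * length(fg) * (mean(bg) - mean(fg))^2
    if (v > best_v + 1e-9) {
      best_v <- v
      best_t <- t
    }
  }
  best_t
}

# per-pixel dilation/erosion with reflect (edge-mirror) padding
brute_morph <- function(mask, se, op) {
  nr <- nrow(mask); nc <- ncol(mask)
  kr <- (nrow(se) - 1L) / 2L; kc <- (ncol(se) - 1L) / 2L
  reflect <- function(i, n) {
    while (i < 1L || i > n) {
      if (i < 1L) i <- 1L - i  # mirror about 0.5: 0 -> 1, -1 -> 2
      if (i > n) i <- 2L * n - i + 1L
    }
    i
  }
  out <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      vals <- integer(0)
      for (dr in -kr:kr) {
        for (dc in -kc:kc) {
          if (!se[dr + kr + 1L, dc + kc + 1L]) next
          vals <- c(vals, mask[reflect(r + dr, nr), reflect(c + dc, nc)])
        }
      }
      out[r, c] <- op(vals)
    }
  }
  out
}

brute_dilate <- function(mask, se) brute_morph(mask, se, max)
brute_erode <- function(mask, se) brute_morph(mask, se, min)

# BFS flood-fill labeling; returns multiset of (area, bbox) per component
flood_fill_objects <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  offs <- if (connectivity == 8L) {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  objs <- list()
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      if (mask[r0, c0] == 0 || seen[r0, c0]) next
      queue <- list(c(r0, c0))
      seen[r0, c0] <- TRUE
      px <- matrix(0L, 0L, 2L)
      while (length(queue) > 0L) {
        cur <- queue[[1L]]; queue <- queue[-1L]
        px <- rbind(px, cur)
        for (k in seq_len(nrow(offs))) {
          rr <- cur[1] + offs[k, 1]; cc <- cur[2] + offs[k, 2]
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              mask[rr, cc] != 0 && !seen[rr, cc]) {
            seen[rr, cc] <- TRUE
            queue[[length(queue) + 1L]] <- c(rr, cc)
          }
        }
      }
      objs[[length(objs) + 1L]] <- c(area = nrow(px),
                                     row_min = min(px[, 1]) - 1L,
                                     col_min = min(px[, 2]) - 1L,
                                     height = diff(range(px[, 1])) + 1L,
                                     width = diff(range(px[, 2])) + 1L)
    }
  }
  objs
}

# sorted multiset of object summaries, comparable across labelers
object_multiset <- function(df_or_list) {
  if (is.data.frame(df_or_list)) {
    m <- df_or_list[, c("area_px", "row_min", "col_min", "height", "width")]
    names(m)[1] <- "area"
  } else {
    m <- as.data.frame(do.call(rbind, df_or_list))
  }
  m <- m[do.call(order, m), , drop = FALSE]
  rownames(m) <- NULL
  m
}

# pair-counting AUC: P(score_pos > score_neg) + 0.5 P(equal)
pair_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (p in sp) tot <- tot + sum(p > sn) + 0.5 * sum(p == sn)
  tot / (length(sp) * length(sn))
}

# exhaustive threshold-enumeration AUPR with step-wise precision
brute_aupr <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  rec <- 0
  area <- 0
  for (t in ths) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    new_rec <- tp / P
    area <- area + (new_rec - rec) * prec
    rec <- new_rec
  }
  area
}

# small random 8-bit test image with >= 2 distinct values
random_test_image <- function(nr = 12L, nc = 12L) {
  repeat {
    m <- matrix(sample(0:255, nr * nc, replace = TRUE,
                       prob = dnorm(0:255, sample(c(60, 180), 1), 50)),
                nr, nc)
    if (length(unique(as.vector(m))) >= 2L) return(m)
  }
}

# tiny score table with both classes
random_score_table <- function(n = 12L, ties = TRUE) {
  repeat {
    sc <- if (ties) sample(seq(0, 1, by = 0.1), n, replace = TRUE) else runif(n)
    lb <- sample(0:1, n, replace = TRUE)
    if (length(unique(lb)) == 2L) {
      return(data.frame(item_path = sprintf("it%02d", seq_len(n)),
                        patient_id = "P", true_label = lb, score = sc))
    }
  }
}
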