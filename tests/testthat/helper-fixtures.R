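# shared fixtures: small images, masks and oracles built in code

# uniform test image
flat_image <- function(value = 0.5, n = 64L, mmpp = 0.05, ...) {
  faf_image(matrix(value, n, n), mmpp, ...)
}

# binary disk mask about (cx, cy) in pixels
disk_mask <- function(n, cx, cy, r_px, feature = "hypo_AF") {
  m <- outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, "+") <= r_px^2
  feature_mask(m, feature)
}

# annulus sector mask: radii [r0, r1) px, angles [a0, a1) radians about center
annulus_mask <- function(n, cx, cy, r0, r1, a0 = 0, a1 = 2 * pi,
                         feature = "ring") {
  dx <- outer(rep(1, n), seq_len(n) - cx)
  dy <- outer(seq_len(n) - cy, rep(1, n))
  r <- sqrt(dx^2 + dy^2)
  ang <- (atan2(dy, dx) + 2 * pi) %% (2 * pi)
  feature_mask(r >= r0 & r < r1 & ang >= a0 & ang < a1, feature)
}

# reference 8-connected component count: queue-based flood fill
flood_count8 <- function(m) {
  m <- m != 0
  seen <- matrix(FALSE, nrow(m), ncol(m))
  count <- 0L
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  for (start in which(m & !seen)) {
    if (seen[start]) next
    count <- count + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1L) %% nrow(m) + 1L
      cl <- (cur - 1L) %/% nrow(m) + 1L
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs$dy[k]; cc <- cl + offs$dx[k]
        if (rr >= 1 && rr <= nrow(m) && cc >= 1 && cc <= ncol(m) &&
            m[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue <- c(queue, (cc - 1L) * nrow(m) + rr)
        }
      }
    }
  }
  count
}

# small phantom spec for segmentation tests (same 16.4 mm field, coarser grid)
small_phantom_spec <- function(seed = 1L, noise_sd = 0.02, ...) {
  phantom_spec(size = 384L, mm_per_pixel = 0.0428, seed = seed,
               noise_sd = noise_sd, ...)
}

# minimal long visit table for cohort tests
visit_row <- function(pid, eye, date, ord = 1L, feature = "hypo_AF",
                      present = TRUE, area = 1, gene = "GENE1", age = 30) {
  tibble::tibble(patient_id = pid, eye_id = eye, date = as.Date(date),
                 order_in_day = ord, age = age, gene = gene,
                 feature = feature, present = present, area_mm2 = area)
}
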