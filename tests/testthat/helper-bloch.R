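# Independent isochromat Bloch-simulation oracle for the EPG simulator.
#
# Simulates an ensemble of magnetization vectors with 3x3 rotation matrices;
# ideal spoiling is realized by giving isochromat j a per-TR gradient
# precession of 2*pi*(j - 0.5)/n_iso and averaging the transverse signal.
# No configuration-state bookkeeping is shared with the EPG implementation.

bloch_oracle <- function(t1, t2, prot, n_iso = 200) {
  n <- prot$trs_per_group; G <- prot$n_groups
  a <- prot$flip_schedule_deg * pi / 180
  th <- 2 * pi * (seq_len(n_iso) - 0.5) / n_iso
  M <- matrix(0, 3, n_iso); M[3, ] <- 1
  relax <- function(M, tau) {
    e2 <- exp(-tau / t2); e1 <- exp(-tau / t1)
    M[1, ] <- M[1, ] * e2; M[2, ] <- M[2, ] * e2
    M[3, ] <- M[3, ] * e1 + (1 - e1)
    M
  }
  rotx <- function(M, al) {
    My <- M[2, ] * cos(al) + M[3, ] * sin(al)
    Mz <- -M[2, ] * sin(al) + M[3, ] * cos(al)
    M[2, ] <- My; M[3, ] <- Mz; M
  }
  rotz <- function(M, phi) {
    Mx <- M[1, ] * cos(phi) - M[2, ] * sin(phi)
    My <- M[1, ] * sin(phi) + M[2, ] * cos(phi)
    M[1, ] <- Mx; M[2, ] <- My; M
  }
  sig <- complex(G * n); k <- 0
  for (g in seq_len(G)) {
    M[1, ] <- 0; M[2, ] <- 0; M[3, ] <- -prot$inv_efficiency * M[3, ]
    M <- relax(M, prot$inversion_time_ms)
    for (t in seq_len(n)) {
      M <- rotx(M, a[t])
      Mte <- relax(M, prot$te_ms)
      k <- k + 1
      sig[k] <- mean(complex(real = Mte[1, ], imaginary = Mte[2, ]))
      M <- relax(M, prot$tr_ms)
      M <- rotz(M, th)
    }
    M[1, ] <- 0; M[2, ] <- 0
    M <- relax(M, prot$rest_s * 1000)
  }
  sig
}
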