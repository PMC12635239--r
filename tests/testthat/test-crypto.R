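# independent oracle: extended Euclid for modular inverse
euclid_inverse <- function(e, phi) {
  r0 <- phi; r1 <- e; t0 <- 0; t1 <- 1
  while (r1 != 0) {
    q <- r0 %/% r1
    tmp <- r0 - q * r1; r0 <- r1; r1 <- tmp
    tmp <- t0 - q * t1; t0 <- t1; t1 <- tmp
  }
  if (r0 != 1) stop("not coprime")
  t0 %% phi
}

# independent oracle: m^e mod N by e-fold multiplication (no squaring)
naive_powmod <- function(m, e, N) {
  out <- 1
  for (i in seq_len(e)) out <- (out * m) %% N
  out
}

test_that("textbook RSA arithmetic matches extended-Euclid and powmod oracles", {
  p <- 61; q <- 53; N <- p * q; phi <- (p - 1) * (q - 1); e <- 17
  expect_equal(N, 3233)
  d <- euclid_inverse(e, phi)
  expect_equal(d, 2753)
  expect_equal((d * e) %% phi, 1)
  # encryption of m = 65 under (e, N), against the naive oracle
  expect_equal(naive_powmod(65, e, N), 2790)
  expect_equal(textbook_rsa_encrypt(65, e, N), 2790)
  expect_equal(textbook_rsa_decrypt(2790, d, N), 65)
  # full cycle over several messages
  for (m in c(0, 1, 42, 1000, 3232)) {
    expect_equal(textbook_rsa_decrypt(textbook_rsa_encrypt(m, e, N), d, N), m)
  }
})

test_that("generated key pairs satisfy the RSA invariants", {
  kp <- test_keypair()
  par <- keypair_params(kp)
  one <- openssl::bignum(1)
  expect_identical(as.character(par$p * par$q), as.character(par$N))
  # modern RSA keys take d = e^-1 mod lcm(p-1, q-1) (Carmichael's function)
  # rather than mod (p-1)(q-1); the two agree in the decryption identity.
  # d*e = 1 (mod p-1) and (mod q-1) is equivalent to d*e = 1 (mod lcm).
  de <- par$d * par$e
  expect_identical(as.character(de %% (par$p - one)), as.character(one))
  expect_identical(as.character(de %% (par$q - one)), as.character(one))
  # public part exports to standard PEM
  priv <- tempfile(fileext = ".pem"); pub <- tempfile(fileext = ".pem")
  write_keypair_pem(kp, priv, pub)
  expect_match(readLines(pub, n = 1), "BEGIN PUBLIC KEY")
  expect_identical(as.character(read_public_key_pem(pub)$data$n),
                   as.character(par$N))
  expect_error(rsa_generate_keypair(1024), "unsupported")
})

test_that("OAEP encryption round-trips, randomizes, and detects tampering", {
  kp <- test_keypair()
  msg <- as.raw(1:32)
  ct1 <- rsa_encrypt_bytes(msg, kp)
  ct2 <- rsa_encrypt_bytes(msg, kp)
  expect_length(ct1, 256)                      # 2048-bit key -> 256 bytes
  expect_false(identical(ct1, ct2))            # randomized padding
  expect_identical(rsa_decrypt_bytes(ct1, kp), msg)
  expect_identical(rsa_decrypt_bytes(ct2, kp), msg)
  # property: exact inverse over random messages
  set.seed(1)
  for (len in sample(1:214, 5)) {
    m <- as.raw(sample(0:255, len, replace = TRUE))
    expect_identical(rsa_decrypt_bytes(rsa_encrypt_bytes(m, kp), kp), m)
  }
  expect_error(rsa_encrypt_bytes(as.raw(rep(1, 215)), kp), "too long")
  # wrong key and tampering
  other <- rsa_generate_keypair(2048)
  expect_error(rsa_decrypt_bytes(ct1, other), "decryption failed")
  bad <- ct1
  bad[10] <- as.raw(bitwXor(as.integer(bad[10]), 1L))
  expect_error(rsa_decrypt_bytes(bad, kp), "decryption failed")
})

test_that("byte-to-bpm map covers exactly [60, 160] over all byte values", {
  f <- bytes_to_bpm(0:255)
  expect_true(all(f >= 60 & f <= 160))
  expect_equal(bytes_to_bpm(0), 60)
  expect_equal(bytes_to_bpm(100), 160)
  expect_equal(bytes_to_bpm(101), 60)
  expect_equal(bytes_to_bpm(255), 113)         # (255 mod 101) + 60
  expect_setequal(unique(f), 60:160)
})

test_that("derived frequency lists have ciphertext length and differ run to run", {
  kp <- test_keypair()
  sch <- derive_frequency_list("clip_0001.avi", kp)
  expect_s3_class(sch, "frequency_schedule")
  expect_length(sch$frequencies_bpm, 256)      # one per ciphertext byte
  expect_true(all(sch$frequencies_bpm >= 60 & sch$frequencies_bpm <= 160))
  lists <- replicate(10, derive_frequency_list("same seed", kp)$frequencies_bpm,
                     simplify = FALSE)
  for (k in 2:10) expect_false(identical(lists[[k - 1]], lists[[k]]))
  expect_error(derive_frequency_list("", kp), "non-empty")
})

test_that("frequency_schedule validates its fields", {
  expect_error(frequency_schedule(c(100, 170)), "\\[60, 160\\]")
  expect_error(frequency_schedule(59), "\\[60, 160\\]")
  expect_error(frequency_schedule(integer(0)), "at least one")
  expect_error(frequency_schedule(100, segment_seconds = 0), "segment_seconds")
  expect_error(frequency_schedule(100, amplitude = -1), "amplitude")
})

test_that("schedule serialization is an exact inverse and keeps order", {
  sch <- frequency_schedule(c(100, 150, 60, 160), segment_seconds = 8,
                            amplitude = 2, phase_policy = "per_segment_reset")
  back <- deserialize_schedule(serialize_schedule(sch))
  expect_identical(back$frequencies_bpm, sch$frequencies_bpm)
  expect_identical(back$segment_seconds, sch$segment_seconds)
  expect_identical(back$amplitude, sch$amplitude)
  expect_identical(back$phase_policy, sch$phase_policy)
  expect_error(deserialize_schedule(as.raw(c(2, 0, 0, 1, 0, 0, 0, 0, 40))),
               "bad header")
  # fractional fields survive at 0.01 resolution
  sch2 <- frequency_schedule(c(72, 88), segment_seconds = 2.5, amplitude = 1.25)
  back2 <- deserialize_schedule(serialize_schedule(sch2))
  expect_equal(back2$segment_seconds, 2.5)
  expect_equal(back2$amplitude, 1.25)
})

test_that("schedule encryption round-trips (including chunking) and fails closed", {
  kp <- test_keypair()
  sch <- frequency_schedule(c(100, 150), segment_seconds = 8, amplitude = 2)
  ct <- encrypt_schedule(sch, kp)
  expect_equal(length(ct) %% 256, 0)
  back <- decrypt_schedule(ct, kp)
  expect_identical(back$frequencies_bpm, sch$frequencies_bpm)
  expect_identical(back$segment_seconds, sch$segment_seconds)
  expect_identical(back$amplitude, sch$amplitude)
  # 512-entry schedule exceeds one 2048-bit block -> chunked
  big <- frequency_schedule(bytes_to_bpm(rep(0:255, 2)))
  ct_big <- encrypt_schedule(big, kp)
  expect_gt(length(ct_big), 256)
  expect_identical(decrypt_schedule(ct_big, kp)$frequencies_bpm,
                   big$frequencies_bpm)
  # tampering is detected
  bad <- ct
  bad[5] <- as.raw(bitwXor(as.integer(bad[5]), 8L))
  expect_error(decrypt_schedule(bad, kp), "decryption failed")
  expect_error(decrypt_schedule(ct[-1], kp), "block size")
  # file round trip: json and .enc
  jp <- tempfile(fileext = ".json"); ep <- tempfile(fileext = ".enc")
  write_schedule_json(sch, jp)
  expect_identical(read_schedule_json(jp)$frequencies_bpm, sch$frequencies_bpm)
  write_encrypted_schedule(ct, ep)
  expect_identical(read_encrypted_schedule(ep), ct)
})
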