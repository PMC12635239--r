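#' Generate an RSA key pair for schedule encryption
#'
#' Creates an RSA key pair used to encrypt fake-heartbeat frequency schedules
#' and to derive randomized frequency lists. The default 4096-bit modulus
#' yields 512-byte ciphertext blocks, i.e. 512 frequencies per derivation.
#'
#' @param key_size_bits Modulus size in bits; one of 2048 or 4096.
#' @return An object of class `pc_keypair`: a list with elements `key`
#'   (the openssl private key), `pubkey` (the public part) and
#'   `key_size_bits`.
#' @examples
#' kp <- rsa_generate_keypair(2048)
#' keypair_params(kp)$N
#' @export
rsa_generate_keypair <- function(key_size_bits = 4096) {
  if (!key_size_bits %in% c(2048L, 4096L)) {
    stop("unsupported RSA key size: ", key_size_bits,
         " (supported: 2048, 4096)", call. = FALSE)
  }
  key <- openssl::rsa_keygen(bits = key_size_bits)
  structure(
    list(key = key, pubkey = key$pubkey, key_size_bits = as.integer(key_size_bits)),
    class = "pc_keypair"
  )
}

#' @export
print.pc_keypair <- function(x, ...) {
  cat("RSA key pair (", x$key_size_bits, " bits, ciphertext block ",
      x$key_size_bits %/% 8L, " bytes)\n", sep = "")
  invisible(x)
}

#' Extract the arithmetic components of an RSA key pair
#'
#' Returns the textbook RSA quantities as openssl big numbers so the key
#' invariants (N = p*q, d*e = 1 mod (p-1)(q-1)) can be verified directly.
#'
#' @param keypair A `pc_keypair`.
#' @return List with bignum elements `p`, `q`, `N`, `e`, `d`.
#' @export
keypair_params <- function(keypair) {
  stopifnot(inherits(keypair, "pc_keypair"))
  d <- keypair$key$data
  list(p = d$p, q = d$q, N = d$n, e = d$e, d = d$d)
}

#' Write / read PEM-encoded keys
#'
#' @param keypair A `pc_keypair`.
#' @param private_path,public_path Destination file paths.
#' @return `write_keypair_pem` invisibly returns the two paths.
#' @export
write_keypair_pem <- function(keypair, private_path, public_path) {
  stopifnot(inherits(keypair, "pc_keypair"))
  openssl::write_pem(keypair$key, private_path)
  openssl::write_pem(keypair$pubkey, public_path)
  invisible(c(private = private_path, public = public_path))
}

#' @rdname write_keypair_pem
#' @param path Path of a PEM file.
#' @export
read_public_key_pem <- function(path) openssl::read_pubkey(path)

#' @rdname write_keypair_pem
#' @export
read_private_key_pem <- function(path) {
  key <- openssl::read_key(path)
  structure(
    list(key = key, pubkey = key$pubkey, key_size_bits = as.integer(key$size)),
    class = "pc_keypair"
  )
}

as_pubkey <- function(public) {
  if (inherits(public, "pc_keypair")) return(public$pubkey)
  public
}

pubkey_bytes <- function(pubkey) as.integer(pubkey$size) %/% 8L

# OAEP (SHA-1 mask) payload overhead per RSA block, in bytes.
OAEP_OVERHEAD <- 42L

#' RSA encryption and decryption of byte strings
#'
#' `rsa_encrypt_bytes` encrypts with OAEP padding, so repeated encryption of
#' the same message yields different ciphertexts; the ciphertext length
#' equals the key size in bytes. `rsa_decrypt_bytes` inverts it and raises a
#' decryption error on a wrong key or tampered ciphertext.
#'
#' @param message Raw vector; at most key_bytes - 42 bytes (OAEP limit).
#' @param public A `pc_keypair` or an openssl public key.
#' @param ciphertext Raw vector as returned by `rsa_encrypt_bytes`.
#' @param private A `pc_keypair`.
#' @return Raw vector.
#' @export
rsa_encrypt_bytes <- function(message, public) {
  pub <- as_pubkey(public)
  stopifnot(is.raw(message))
  limit <- pubkey_bytes(pub) - OAEP_OVERHEAD
  if (length(message) > limit) {
    stop("message too long for RSA-OAEP block: ", length(message),
         " > ", limit, " bytes", call. = FALSE)
  }
  openssl::rsa_encrypt(message, pub, oaep = TRUE)
}

#' @rdname rsa_encrypt_bytes
#' @export
rsa_decrypt_bytes <- function(ciphertext, private) {
  stopifnot(inherits(private, "pc_keypair"), is.raw(ciphertext))
  out <- tryCatch(
    openssl::rsa_decrypt(ciphertext, private$key, oaep = TRUE),
    error = function(e) {
      stop("RSA decryption failed (wrong key or tampered ciphertext): ",
           conditionMessage(e), call. = FALSE)
    }
  )
  out
}

#' Textbook modular exponentiation (toy moduli)
#'
#' Computes `base^exp mod m` by square-and-multiply with exact double
#' arithmetic; valid for moduli below 2^26 so intermediate products stay
#' exactly representable. This is the unpadded schoolbook form of the RSA
#' maps M = m^e mod N and m = M^d mod N, kept for arithmetic verification
#' on small parameters; production encryption always uses OAEP padding.
#'
#' @param base,exp,m Non-negative integers, `m < 2^26`.
#' @return `base^exp mod m` as a double holding an exact integer.
#' @export
modpow <- function(base, exp, m) {
  stopifnot(m >= 1, m < 2^26, exp >= 0)
  base <- base %% m
  result <- 1
  while (exp > 0) {
    if (exp %% 2 == 1) result <- (result * base) %% m
    base <- (base * base) %% m
    exp <- exp %/% 2
  }
  result
}

#' @rdname modpow
#' @param message_int,e,N,d,ciphertext_int Toy RSA integers.
#' @export
textbook_rsa_encrypt <- function(message_int, e, N) modpow(message_int, e, N)

#' @rdname modpow
#' @export
textbook_rsa_decrypt <- function(ciphertext_int, d, N) modpow(ciphertext_int, d, N)

#' Fake-heartbeat frequency schedule
#'
#' A schedule is an ordered list of fake heart-rate frequencies (beats per
#' minute, each in \[60, 160\]), one per time segment of `segment_seconds`,
#' together with the modulation amplitude in grey levels and the phase
#' policy used when the driving sinusoid crosses segment boundaries.
#'
#' @param frequencies_bpm Integer vector, every entry in \[60, 160\].
#' @param segment_seconds Positive duration of each segment (seconds).
#' @param amplitude Positive modulation amplitude (grey levels).
#' @param phase_policy `"continuous"` accumulates phase across segment
#'   boundaries (no visible discontinuity); `"per_segment_reset"` evaluates
#'   each segment's sinusoid at global elapsed time.
#' @return Object of class `frequency_schedule`.
#' @export
frequency_schedule <- function(frequencies_bpm,
                               segment_seconds = 8,
                               amplitude = 2,
                               phase_policy = c("continuous", "per_segment_reset")) {
  phase_policy <- match.arg(phase_policy)
  f <- as.integer(round(frequencies_bpm))
  if (length(f) < 1L) stop("schedule needs at least one frequency", call. = FALSE)
  if (any(f < 60L | f > 160L)) {
    stop("frequencies must lie in [60, 160] bpm", call. = FALSE)
  }
  if (!is.numeric(segment_seconds) || segment_seconds <= 0) {
    stop("segment_seconds must be > 0", call. = FALSE)
  }
  if (!is.numeric(amplitude) || amplitude <= 0) {
    stop("amplitude must be > 0", call. = FALSE)
  }
  structure(
    list(frequencies_bpm = f,
         segment_seconds = as.numeric(segment_seconds),
         amplitude = as.numeric(amplitude),
         phase_policy = phase_policy),
    class = "frequency_schedule"
  )
}

#' @export
print.frequency_schedule <- function(x, ...) {
  n <- length(x$frequencies_bpm)
  head_f <- paste(utils::head(x$frequencies_bpm, 6), collapse = ", ")
  cat("Fake-heartbeat frequency schedule\n",
      "  ", n, " segment(s) of ", x$segment_seconds, " s: [", head_f,
      if (n > 6) ", ..." else "", "] bpm\n",
      "  amplitude ", x$amplitude, " grey levels, phase ", x$phase_policy,
      "\n", sep = "")
  invisible(x)
}

#' Derive a randomized frequency list from a seed string
#'
#' Encrypts `seed_string` with the sender's public key (OAEP, hence
#' randomized) and maps each ciphertext byte b to `(b mod 101) + 60`,
#' giving one frequency in \[60, 160\] bpm per ciphertext byte. A 4096-bit
#' key yields a 512-byte ciphertext and therefore 512 frequencies. Because
#' the padding is randomized, repeated calls with identical inputs produce
#' different lists.
#'
#' @inheritParams rsa_encrypt_bytes
#' @param seed_string Non-empty character scalar.
#' @param segment_seconds,amplitude,phase_policy Passed to
#'   [frequency_schedule()].
#' @return A [frequency_schedule()] of length = ciphertext bytes.
#' @export
derive_frequency_list <- function(seed_string, public,
                                  segment_seconds = 8, amplitude = 2,
                                  phase_policy = "continuous") {
  if (!is.character(seed_string) || length(seed_string) != 1L ||
      !nzchar(seed_string)) {
    stop("seed_string must be a non-empty string", call. = FALSE)
  }
  ct <- rsa_encrypt_bytes(charToRaw(seed_string), public)
  frequency_schedule(bytes_to_bpm(as.integer(ct)),
                     segment_seconds = segment_seconds,
                     amplitude = amplitude,
                     phase_policy = phase_policy)
}

#' @rdname derive_frequency_list
#' @param byte_values Integer vector in \[0, 255\].
#' @export
bytes_to_bpm <- function(byte_values) {
  stopifnot(all(byte_values >= 0L & byte_values <= 255L))
  (byte_values %% 101L) + 60L
}

# --- canonical wire format ----------------------------------------------
# [0] version 0x01
# [1] phase policy: 0 = continuous, 1 = per_segment_reset
# [2:3] uint16 BE: number of frequencies
# [4:5] uint16 BE: round(segment_seconds * 100)
# [6:7] uint16 BE: round(amplitude * 100)
# [8:...] one byte per frequency, offset-encoded as f - 60 (0..100)

uint16_be <- function(x) as.raw(c(x %/% 256L, x %% 256L))
read_uint16_be <- function(r, at) as.integer(r[at]) * 256L + as.integer(r[at + 1L])

#' Serialize / deserialize a frequency schedule
#'
#' Canonical byte layout: version byte, phase-policy byte, then
#' big-endian uint16 fields for count, segment duration (centiseconds) and
#' amplitude (hundredths of a grey level), then one offset-encoded byte
#' (frequency - 60) per entry.
#'
#' @param schedule A [frequency_schedule()].
#' @return `serialize_schedule`: a raw vector; `deserialize_schedule`: the
#'   schedule reconstructed exactly (to 0.01 resolution in t and A).
#' @export
serialize_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "frequency_schedule"))
  n <- length(schedule$frequencies_bpm)
  if (n > 65535L) stop("schedule too long to serialize", call. = FALSE)
  t100 <- as.integer(round(schedule$segment_seconds * 100))
  a100 <- as.integer(round(schedule$amplitude * 100))
  if (t100 > 65535L || a100 > 65535L) {
    stop("segment_seconds/amplitude out of serializable range", call. = FALSE)
  }
  c(as.raw(0x01),
    as.raw(if (schedule$phase_policy == "continuous") 0L else 1L),
    uint16_be(n), uint16_be(t100), uint16_be(a100),
    as.raw(schedule$frequencies_bpm - 60L))
}

#' @rdname serialize_schedule
#' @param payload Raw vector produced by `serialize_schedule`.
#' @export
deserialize_schedule <- function(payload) {
  stopifnot(is.raw(payload))
  if (length(payload) < 9L || payload[1] != as.raw(0x01)) {
    stop("not a serialized frequency schedule (bad header)", call. = FALSE)
  }
  policy <- if (payload[2] == as.raw(0)) "continuous" else "per_segment_reset"
  n <- read_uint16_be(payload, 3L)
  if (length(payload) != 8L + n) {
    stop("corrupt schedule payload: length mismatch", call. = FALSE)
  }
  frequency_schedule(
    as.integer(payload[9:(8L + n)]) + 60L,
    segment_seconds = read_uint16_be(payload, 5L) / 100,
    amplitude = read_uint16_be(payload, 7L) / 100,
    phase_policy = policy
  )
}

#' Encrypt / decrypt a frequency schedule for the receiver
#'
#' The serialized schedule is RSA-OAEP-encrypted with the receiver's public
#' key. Payloads longer than one RSA block are chunked; the ciphertext is
#' the concatenation of fixed-size blocks (any schedule length supported).
#'
#' @param schedule A [frequency_schedule()].
#' @param receiver_public Receiver's public key (`pc_keypair` or openssl
#'   pubkey).
#' @return Raw ciphertext (a multiple of the key size in bytes).
#' @export
encrypt_schedule <- function(schedule, receiver_public) {
  pub <- as_pubkey(receiver_public)
  payload <- serialize_schedule(schedule)
  chunk <- pubkey_bytes(pub) - OAEP_OVERHEAD
  starts <- seq(1L, length(payload), by = chunk)
  blocks <- lapply(starts, function(s) {
    rsa_encrypt_bytes(payload[s:min(s + chunk - 1L, length(payload))], pub)
  })
  do.call(c, blocks)
}

#' @rdname encrypt_schedule
#' @param ciphertext Raw vector from `encrypt_schedule`.
#' @param receiver_private The receiver's `pc_keypair`.
#' @export
decrypt_schedule <- function(ciphertext, receiver_private) {
  stopifnot(inherits(receiver_private, "pc_keypair"), is.raw(ciphertext))
  bs <- receiver_private$key_size_bits %/% 8L
  if (length(ciphertext) %% bs != 0L) {
    stop("ciphertext length is not a multiple of the RSA block size",
         call. = FALSE)
  }
  starts <- seq(1L, length(ciphertext), by = bs)
  payload <- do.call(c, lapply(starts, function(s) {
    rsa_decrypt_bytes(ciphertext[s:(s + bs - 1L)], receiver_private)
  }))
  deserialize_schedule(payload)
}

#' Plain-text schedule I/O
#'
#' JSON for the human-readable plaintext schedule, a binary `.enc` file for
#' the encrypted schedule.
#'
#' @param schedule A [frequency_schedule()].
#' @param path File path.
#' @export
write_schedule_json <- function(schedule, path) {
  stopifnot(inherits(schedule, "frequency_schedule"))
  jsonlite::write_json(unclass(schedule), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
read_schedule_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  frequency_schedule(x$frequencies_bpm, x$segment_seconds, x$amplitude,
                     x$phase_policy)
}

#' @rdname write_schedule_json
#' @param ciphertext Raw vector.
#' @export
write_encrypted_schedule <- function(ciphertext, path) {
  stopifnot(is.raw(ciphertext))
  writeBin(ciphertext, path)
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
read_encrypted_schedule <- function(path) {
  readBin(path, "raw", n = file.size(path))
}
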