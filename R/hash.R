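# Stable content hashes for provenance manifests and config fingerprints.
# Objects are serialized with a fixed format version so the hash depends only
# on the value, then digested with md5.
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2L, xdr = TRUE)
  close(con)
  unname(tools::md5sum(f))
}

hash_file <- function(path) unname(tools::md5sum(path))
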