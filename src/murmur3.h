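#ifndef READFORMER_MURMUR3_H
#define READFORMER_MURMUR3_H

#include <cstdint>
#include <cstddef>

// MurmurHash3 x64_128 (Austin Appleby's public-domain algorithm).
void murmur3_x64_128(const void *key, int len, uint32_t seed, uint64_t out[2]);

// Low 64 bits of the 128-bit hash, reduced modulo m.
uint64_t murmur3_mod(const char *s, int len, uint32_t seed, uint64_t m);

#endif
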