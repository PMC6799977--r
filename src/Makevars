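# Build with the system toolchain: the bundled cross-compiler targets a
# newer glibc sysroot than the process dynamic loader provides, so its
# objects fail at dyn.load time with unresolved versioned symbols.
override CC = gcc
override CXX = g++
override CXX11 = g++
override CXX14 = g++
override CXX17 = g++
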