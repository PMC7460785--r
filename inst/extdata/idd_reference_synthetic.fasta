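>IDDref1 synthetic IDD-type C2H2 reference finger
FACPECGKSFSTRNVRSSHLRAH
>IDDref2 synthetic IDD-type C2H2 reference finger
FACDQCGKSFSTRNVRSSHLRAH
>IDDref3 synthetic IDD-type C2H2 reference finger
FACPECGKGFATRNVRSSHLKAH
>IDDref4 synthetic IDD-type C2H2 reference finger
FACPECGKSFSRRNVRSSHLRAH
>IDDref5 synthetic IDD-type C2H2 reference finger
FACDECGKSYSTRNVRSSHLRAH
>IDDref6 synthetic IDD-type C2H2 reference finger
FACPQCGKSFSTTNVRSSHLKAH
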