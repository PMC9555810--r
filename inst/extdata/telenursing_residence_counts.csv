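attribute_id,group,m,o,a,i,q,r,n,z_published,p_published
1,Rural,4,16,81,65,4,3,173,0.85,0.4
1,Urban,4,18,89,57,3,4,175,0.85,0.4
2,Rural,2,14,81,71,2,3,173,1.74,0.08
2,Urban,2,19,93,57,4,0,175,1.74,0.08
3,Rural,2,16,83,60,4,8,173,0.92,0.36
3,Urban,2,20,87,57,4,5,175,0.92,0.36
4,Rural,4,17,83,64,2,3,173,0.74,0.46
4,Urban,7,20,82,62,3,1,175,0.74,0.46
5,Rural,5,18,83,61,2,4,173,0.34,0.74
5,Urban,6,18,86,60,4,1,175,0.34,0.74
6,Rural,53,40,35,40,3,2,173,0.54,0.59
6,Urban,52,48,38,33,4,0,175,0.54,0.59
7,Rural,2,84,39,40,3,5,173,0.22,0.82
7,Urban,4,82,43,41,1,4,175,0.22,0.82
8,Rural,4,92,44,31,1,1,173,0.58,0.56
8,Urban,3,101,40,28,3,0,175,0.58,0.56
9,Rural,2,17,66,81,4,3,173,0.02,0.98
9,Urban,3,23,54,91,1,3,175,0.02,0.98
10,Rural,3,19,64,82,3,2,173,0.58,0.56
10,Urban,2,20,59,88,5,1,175,0.58,0.56
11,Rural,79,23,39,27,3,2,173,0.98,0.33
11,Urban,88,25,33,26,2,1,175,0.98,0.33
12,Rural,75,30,34,32,1,1,173,0.33,0.74
12,Urban,78,34,29,31,3,0,175,0.33,0.74
13,Rural,3,93,46,26,2,3,173,1.28,0.2
13,Urban,3,108,36,22,2,4,175,1.28,0.2
14,Rural,3,94,45,26,3,2,173,0.78,0.44
14,Urban,4,100,43,28,0,0,175,0.78,0.44
15,Rural,4,93,45,28,2,1,173,0.78,0.44
15,Urban,3,103,43,21,2,3,175,0.78,0.44
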