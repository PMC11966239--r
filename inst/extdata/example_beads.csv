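"x","y","z","amplitude","width"
-2.541,1.161,-4.823,1,2
1.634,0.398,0.734,1,2
2.848,-0.544,-1.632,1,2
1.819,-5.374,2.655,1,2
-0.478,2.754,6.446,1,2
6.802,-0.977,-4.467,1,2
-0.426,-0.822,2.046,1,2
-0.282,3.698,4.03,1,2
5.872,6.265,-1.034,1,2
-0.6,-4.999,3.892,1,2
2.862,-3.874,-0.678,1,2
-1.279,-5.093,-6.521,1,2
5.941,2.939,-0.029,1,2
-1.38,5.404,0.682,1,2
-0.774,-4.514,1.66,1,2
-1.937,0.475,-6.013,1,2
-1.158,-1.9,3.153,1,2
-7.934,-0.551,2.494,1,2
2.07,0.847,-3.763,1,2
-2.88,0.536,-7.176,1,2
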