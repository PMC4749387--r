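suture	group	emu	alligator
nasal-mesethmoid	facial	x
nasal-prefrontal	facial	x	x
nasal-frontal	facial	x	x
nasal-premaxilla	facial	x	x
frontal-mesethmoid	facial	x
internasal	facial		x
nasal-maxilla	facial		x
maxilla-jugal	facial		x
maxilla-premaxilla	facial		x
maxilla-lachrymal	facial		x
prefrontal-lachrymal	facial		x
lachrymal-jugal	facial		x
frontal-prefrontal	facial		x
interpremaxillary	facial		x
interfrontal	cranial	x	x
frontal-parietal	cranial	x	x
interparietal	cranial	x	x
parietal-squamosal	cranial	x	x
supraoccipital-parietal	cranial	x	x
exoccipital-squamosal	cranial	x	x
laterosphenoid-parietal	cranial	x
laterosphenoid-squamosal	cranial	x
frontal-postorbital	cranial		x
postorbital-squamosal	cranial		x
pterygoid-vomer	palatal	x
vomer-palatine	palatal	x
maxilla-premaxilla	palatal	x	x
premaxilla-vomer	palatal	x
intermaxillary	palatal		x
maxilla-palatine	palatal		x
interpalatine	palatal		x
exoccipital-supraoccipital	braincase	x	x
exoccipital-basioccipital	braincase	x	x
laterosphenoid-prootic	braincase		x
laterosphenoid-basisphenoid	braincase		x
laterosphenoid-pterygoid	braincase		x
laterosphenoid-quadrate	braincase		x
basisphenoid-prootic	braincase		x
basisphenoid-basioccipital	braincase	x	x
basisphenoid-pterygoid	braincase		x
exoccipital-prootic	braincase		x
exoccipital-quadrate	braincase		x
quadrate-pterygoid	braincase		x
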